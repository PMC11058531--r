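#' Configure a cohort-structured opinion-change regime
#'
#' A regime describes how birth cohorts' mean opinions are laid out and how
#' they move over the observation window. Three idealised kinds are supported:
#' `"settled"` (cohorts differ in their intercepts but never move, so all
#' aggregate change is cohort replacement), `"within_only"` (all cohorts share
#' one intercept and drift together at a common nonzero rate, so all change is
#' within-cohort), and `"mixed"` (both between-cohort spread and a common
#' within-cohort trend).
#'
#' Individual responses are drawn as
#' `Normal(intercept_c + slope_c * (year - reference_year), noise_sd)`, where
#' the reference year is the midpoint of `[first_year, last_year]` so that
#' intercepts are period-centred. Cohorts are blocks of `cohort_width_years`
#' consecutive birth years placed so that the youngest cohort has reached
#' `min_age` by the first survey wave; every cohort is then observed in every
#' wave (no mortality process).
#'
#' When `cohort_intercepts` / `within_cohort_slopes` are omitted they default
#' to the package's reference conditions: settled intercepts spanning
#' `2 * noise_sd`, within-only common slope `0.05 * noise_sd` per year, mixed
#' intercept spread `1.0` with common slope `0.05`.
#'
#' @param regime one of `"settled"`, `"mixed"`, `"within_only"`.
#' @param n_cohorts number of birth cohorts (positive integer).
#' @param cohort_intercepts numeric vector of cohort mean opinions at the
#'   reference year, oldest cohort first; length `n_cohorts`.
#' @param within_cohort_slopes numeric vector of per-year linear trends, one
#'   per cohort. Must be all zero for `"settled"`; all equal and nonzero, with
#'   equal intercepts, for `"within_only"`.
#' @param noise_sd individual response noise SD (>= 0; zero gives the
#'   deterministic limit).
#' @param first_year,last_year observation window (integers).
#' @param n_waves number of survey waves (>= 2), equally spaced over the
#'   window.
#' @param n_per_cohort_wave respondents drawn per cohort per wave.
#' @param cohort_width_years birth years spanned by each cohort.
#' @param response_bounds optional `c(lo, hi)`; responses are clipped to it.
#' @param discretise if `TRUE`, responses are rounded to integers after
#'   clipping (emulating 1-10 justifiability scales).
#' @param min_age youngest age at which a cohort is surveyed (default 18).
#' @param staggered_entry if `FALSE` (default) cohort blocks are placed so
#'   every cohort is of age by the first wave and appears in all waves, giving
#'   exactly `n_waves * n_cohorts * n_per_cohort_wave` rows. If `TRUE`, the
#'   youngest block comes of age only by the last wave and each cohort enters
#'   the sample at the first wave where its youngest member has reached
#'   `min_age`; composition then shifts toward younger cohorts over time, the
#'   mechanism by which cohort replacement moves the aggregate mean.
#'
#' @return an object of class `regime_config`.
#' @export
#' @examples
#' cfg <- regime_config("settled", noise_sd = 1)
#' cfg$cohort_intercepts
regime_config <- function(regime = c("settled", "mixed", "within_only"),
                          n_cohorts = 5,
                          cohort_intercepts = NULL,
                          within_cohort_slopes = NULL,
                          noise_sd = 1,
                          first_year = 1981,
                          last_year = 2020,
                          n_waves = 8,
                          n_per_cohort_wave = 100,
                          cohort_width_years = 10,
                          response_bounds = NULL,
                          discretise = FALSE,
                          min_age = 18,
                          staggered_entry = FALSE) {
  regime <- match.arg(regime)
  if (n_cohorts < 1) stop_config("n_cohorts must be a positive integer")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (n_waves < 2) stop_config("n_waves must be >= 2: tau needs at least two survey years")
  if (last_year <= first_year) stop_config("last_year must exceed first_year")
  if (n_waves > last_year - first_year + 1) {
    stop_config("n_waves distinct survey years do not fit in [%d, %d]",
                first_year, last_year)
  }
  if (n_per_cohort_wave < 1) stop_config("n_per_cohort_wave must be positive")
  if (cohort_width_years < 1) stop_config("cohort_width_years must be positive")

  if (is.null(cohort_intercepts)) {
    cohort_intercepts <- switch(regime,
      settled = seq(-noise_sd, noise_sd, length.out = n_cohorts),
      mixed = seq(-0.5, 0.5, length.out = n_cohorts),
      within_only = rep(0, n_cohorts)
    )
  }
  if (is.null(within_cohort_slopes)) {
    within_cohort_slopes <- switch(regime,
      settled = rep(0, n_cohorts),
      mixed = rep(0.05, n_cohorts),
      within_only = rep(0.05 * max(noise_sd, 1e-12), n_cohorts)
    )
  }
  if (length(cohort_intercepts) != n_cohorts) {
    stop_config("cohort_intercepts has length %d but n_cohorts is %d",
                length(cohort_intercepts), n_cohorts)
  }
  if (length(within_cohort_slopes) != n_cohorts) {
    stop_config("within_cohort_slopes has length %d but n_cohorts is %d",
                length(within_cohort_slopes), n_cohorts)
  }
  if (regime == "settled" && any(within_cohort_slopes != 0)) {
    stop_config("settled regime requires all within_cohort_slopes to be zero")
  }
  if (regime == "within_only") {
    if (length(unique(cohort_intercepts)) != 1L) {
      stop_config("within_only regime requires all cohort_intercepts equal")
    }
    if (length(unique(within_cohort_slopes)) != 1L ||
        within_cohort_slopes[1] == 0) {
      stop_config("within_only regime requires a common nonzero slope")
    }
  }
  if (!is.null(response_bounds)) {
    if (length(response_bounds) != 2 || response_bounds[1] >= response_bounds[2]) {
      stop_config("response_bounds must be c(lo, hi) with lo < hi")
    }
  }

  structure(
    list(
      regime = regime,
      n_cohorts = as.integer(n_cohorts),
      cohort_intercepts = as.numeric(cohort_intercepts),
      within_cohort_slopes = as.numeric(within_cohort_slopes),
      noise_sd = noise_sd,
      first_year = as.integer(first_year),
      last_year = as.integer(last_year),
      n_waves = as.integer(n_waves),
      n_per_cohort_wave = as.integer(n_per_cohort_wave),
      cohort_width_years = as.integer(cohort_width_years),
      response_bounds = response_bounds,
      discretise = isTRUE(discretise),
      min_age = as.integer(min_age),
      staggered_entry = isTRUE(staggered_entry)
    ),
    class = "regime_config"
  )
}

#' Survey wave years implied by a regime configuration
#'
#' `n_waves` integer years equally spaced over `[first_year, last_year]`.
#'
#' @param config a [regime_config()].
#' @return integer vector of survey years.
#' @export
wave_years <- function(config) {
  yrs <- round(seq(config$first_year, config$last_year,
                   length.out = config$n_waves))
  as.integer(yrs)
}

#' Reference year used to centre within-cohort trends
#'
#' The midpoint of the observation window; cohort intercepts are means at this
#' year, which stabilises the interpretation of the cohort-by-year fit.
#'
#' @param config a [regime_config()].
#' @return numeric year.
#' @export
reference_year <- function(config) {
  (config$first_year + config$last_year) / 2
}

# Birth-year block [start, end] per cohort, oldest first. Default placement
# puts the youngest cohort's latest birth year at first_year - min_age so
# every cohort is adult in wave 1; staggered placement anchors it at
# last_year - min_age so cohorts come of age across the window.
cohort_birth_blocks <- function(config) {
  k <- config$n_cohorts
  w <- config$cohort_width_years
  anchor <- if (config$staggered_entry) config$last_year else config$first_year
  youngest_end <- anchor - config$min_age
  ends <- youngest_end - (k - seq_len(k)) * w
  tibble::tibble(
    cohort = seq_len(k),
    birth_start = as.integer(ends - w + 1L),
    birth_end = as.integer(ends)
  )
}

#' @export
print.regime_config <- function(x, ...) {
  cat(sprintf("<regime_config: %s>\n", x$regime))
  cat(sprintf("  %d cohorts x %d waves (%d-%d), %d per cohort-wave\n",
              x$n_cohorts, x$n_waves, x$first_year, x$last_year,
              x$n_per_cohort_wave))
  cat(sprintf("  intercepts: %s\n",
              paste(signif(x$cohort_intercepts, 3), collapse = ", ")))
  cat(sprintf("  slopes/yr:  %s\n",
              paste(signif(x$within_cohort_slopes, 3), collapse = ", ")))
  cat(sprintf("  noise_sd %.3g%s\n", x$noise_sd,
              if (x$discretise) ", discretised" else ""))
  invisible(x)
}

#' Configure a synthetic item-sensitivity rating survey
#'
#' Emulates a multi-country online survey in which each respondent rates how
#' difficult each issue would be for the majority of their compatriots to
#' discuss, on a 1-10 scale (1 = not difficult at all, 10 = extremely
#' difficult), with a small battery of attention checks.
#'
#' @param latent_sensitivity a tibble with columns `country`, `item`,
#'   `latent` giving each item's true country-level difficulty on the 1-10
#'   scale.
#' @param n_respondents_per_country respondents recruited per country.
#' @param rating_noise_sd SD of respondent-level rating noise (>= 0).
#' @param n_attention_checks number of attention checks shown (>= 0).
#' @param p_miss_check probability a respondent misses any one check.
#'
#' @return an object of class `sensitivity_survey_config`.
#' @export
sensitivity_survey_config <- function(latent_sensitivity,
                                      n_respondents_per_country = 100,
                                      rating_noise_sd = 1.5,
                                      n_attention_checks = 4,
                                      p_miss_check = 0.05) {
  latent_sensitivity <- tibble::as_tibble(latent_sensitivity)
  assert_columns(latent_sensitivity, c("country", "item", "latent"),
                 "latent_sensitivity")
  if (nrow(latent_sensitivity) == 0) {
    stop_config("latent_sensitivity must contain at least one item")
  }
  if (any(latent_sensitivity$latent < 1 | latent_sensitivity$latent > 10)) {
    stop_config("latent sensitivities must lie on the 1-10 rating scale")
  }
  if (rating_noise_sd < 0) stop_config("rating_noise_sd must be >= 0")
  if (n_attention_checks < 0) stop_config("n_attention_checks must be >= 0")
  if (p_miss_check < 0 || p_miss_check > 1) {
    stop_config("p_miss_check must be a probability in [0, 1]")
  }
  structure(
    list(
      latent_sensitivity = latent_sensitivity,
      n_respondents_per_country = as.integer(n_respondents_per_country),
      rating_noise_sd = rating_noise_sd,
      n_attention_checks = as.integer(n_attention_checks),
      p_miss_check = p_miss_check
    ),
    class = "sensitivity_survey_config"
  )
}

#' Configure a joint opinion + sensitivity study
#'
#' Defines the study conditions for an end-to-end synthetic study: a grid of
#' items and countries, latent item sensitivities, and a coupling
#' (`mixing_effect`, on the log-odds scale) between an item's standardised
#' sensitivity and the probability that its opinion trajectory follows the
#' settled (cohort-replacement-only) regime rather than the within-cohort
#' alternative. Defaults mirror a scaled-down WVS-style design: 56 items in 8
#' countries observed 1981-2020.
#'
#' @param n_items number of survey items.
#' @param countries character vector of country codes.
#' @param mixing_effect true log-odds effect of standardised sensitivity on
#'   the probability of the settled regime.
#' @param settled a [regime_config()] used for settled-regime items.
#' @param alternative a [regime_config()] used for the remaining items
#'   (default: the within-only reference regime).
#' @param n_respondents_per_country,rating_noise_sd,n_attention_checks,p_miss_check
#'   passed to [sensitivity_survey_config()].
#' @param seed integer seed making the whole study reproducible.
#'
#' @return an object of class `joint_study_config`.
#' @export
joint_study_config <- function(n_items = 56,
                               countries = c("ARG", "AUS", "CAN", "JPN",
                                             "MEX", "ZAF", "SWE", "USA"),
                               mixing_effect = 2,
                               settled = regime_config("settled"),
                               alternative = regime_config("within_only"),
                               n_respondents_per_country = 100,
                               rating_noise_sd = 1.5,
                               n_attention_checks = 4,
                               p_miss_check = 0.05,
                               seed = 1) {
  if (n_items < 1) stop_config("n_items must be positive")
  if (length(countries) < 1) stop_config("at least one country is required")
  stopifnot(inherits(settled, "regime_config"),
            inherits(alternative, "regime_config"))
  if (settled$regime != "settled") {
    stop_config("`settled` must be a settled-regime configuration")
  }
  structure(
    list(
      n_items = as.integer(n_items),
      countries = as.character(countries),
      mixing_effect = mixing_effect,
      settled = settled,
      alternative = alternative,
      n_respondents_per_country = as.integer(n_respondents_per_country),
      rating_noise_sd = rating_noise_sd,
      n_attention_checks = as.integer(n_attention_checks),
      p_miss_check = p_miss_check,
      seed = as.integer(seed)
    ),
    class = "joint_study_config"
  )
}
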