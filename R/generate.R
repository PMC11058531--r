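#' Generate cohort-structured repeated cross-sectional opinion data
#'
#' Draws a long-format opinion table under a [regime_config()]. For every
#' survey wave and every cohort, `n_per_cohort_wave` respondents are sampled:
#' birth year uniform within the cohort's block, response
#' `Normal(intercept_c + slope_c * (year - reference_year), noise_sd)`,
#' clipped to `response_bounds` (and rounded when `discretise`). With the
#' default cohort placement the output has exactly
#' `n_waves * n_cohorts * n_per_cohort_wave` rows; with `staggered_entry`
#' each cohort contributes only from the wave where it comes of age. Output
#' is deterministic for a fixed seed.
#'
#' @param config a [regime_config()].
#' @param country country code stamped on every row.
#' @param item item id stamped on every row.
#' @param seed integer seed.
#'
#' @return tibble with columns `country`, `survey_year`, `birth_year`,
#'   `item`, `response`.
#' @export
#' @examples
#' op <- generate_opinion_data(regime_config("settled"), "USA", "item01", 1)
#' dplyr::count(op, survey_year)
generate_opinion_data <- function(config, country = "USA", item = "item",
                                  seed = 1) {
  stopifnot(inherits(config, "regime_config"))
  years <- wave_years(config)
  ref <- reference_year(config)
  blocks <- cohort_birth_blocks(config)
  n_per <- config$n_per_cohort_wave

  cells <- tidyr::expand_grid(survey_year = years, cohort = blocks$cohort)
  if (config$staggered_entry) {
    # a cohort is sampled once its youngest member has reached min_age
    of_age <- blocks$birth_end[cells$cohort] + config$min_age <=
      cells$survey_year
    cells <- cells[of_age, ]
  }
  idx <- rep(seq_len(nrow(cells)), each = n_per)
  cohort <- cells$cohort[idx]
  year <- cells$survey_year[idx]
  mu <- config$cohort_intercepts[cohort] +
    config$within_cohort_slopes[cohort] * (year - ref)

  withr::with_seed(seed, {
    width <- config$cohort_width_years
    birth <- blocks$birth_start[cohort] +
      as.integer(floor(runif(length(idx)) * width))
    response <- rnorm(length(idx), mean = mu, sd = config$noise_sd)
    if (!is.null(config$response_bounds)) {
      response <- clip(response, config$response_bounds[1],
                       config$response_bounds[2])
    }
    if (config$discretise) {
      response <- round(response)
      if (!is.null(config$response_bounds)) {
        response <- clip(response, config$response_bounds[1],
                         config$response_bounds[2])
      }
    }
    tibble::tibble(
      country = country,
      survey_year = as.integer(year),
      birth_year = as.integer(birth),
      item = item,
      response = response
    )
  })
}

#' Generate a synthetic sensitivity-rating survey
#'
#' Every respondent rates every item of their country:
#' `rating = round(latent + Normal(0, rating_noise_sd))` clipped to 1-10.
#' Attention-check misses are `Binomial(n_attention_checks, p_miss_check)`
#' per respondent. Deterministic for a fixed seed.
#'
#' @param config a [sensitivity_survey_config()].
#' @param seed integer seed.
#'
#' @return tibble with columns `respondent_id`, `country`, `item`, `rating`,
#'   `n_checks_missed`.
#' @export
generate_sensitivity_survey <- function(config, seed = 1) {
  stopifnot(inherits(config, "sensitivity_survey_config"))
  lat <- config$latent_sensitivity
  countries <- unique(lat$country)
  n_resp <- config$n_respondents_per_country

  withr::with_seed(seed, {
    out <- lapply(countries, function(cc) {
      items <- lat[lat$country == cc, ]
      ids <- sprintf("%s_%03d", cc, seq_len(n_resp))
      miss <- rbinom(n_resp, config$n_attention_checks, config$p_miss_check)
      grid <- tidyr::expand_grid(respondent_id = ids, item = items$item)
      latent <- items$latent[match(grid$item, items$item)]
      rating <- round(latent + rnorm(nrow(grid), 0, config$rating_noise_sd))
      tibble::tibble(
        respondent_id = grid$respondent_id,
        country = cc,
        item = grid$item,
        rating = as.integer(clip(rating, 1, 10)),
        n_checks_missed = as.integer(miss[match(grid$respondent_id, ids)])
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Generate a full joint study: opinions, ratings, and ground truth
#'
#' For each item-country pair, a latent sensitivity is drawn (an item-level
#' base uniform on 2-9 plus country-level jitter, clipped to the 1-10 scale)
#' and standardised across all pairs. The pair's opinion regime is then drawn
#' Bernoulli with `P(settled) = plogis(mixing_effect * z)`, opinions are
#' generated from the corresponding regime configuration, and a sensitivity
#' survey is generated from the latent values. The truth table records the
#' generative regime and parameters per pair, enabling parameter-recovery
#' tests of the downstream mixture model.
#'
#' @param config a [joint_study_config()].
#'
#' @return a list with elements `opinions`, `ratings`, `truth` (tibbles).
#' @export
#' @examples
#' \donttest{
#' study <- generate_joint_study(joint_study_config(n_items = 4,
#'   countries = c("USA", "SWE"), seed = 1))
#' study$truth
#' }
generate_joint_study <- function(config) {
  stopifnot(inherits(config, "joint_study_config"))
  items <- sprintf("item%02d", seq_len(config$n_items))

  truth <- withr::with_seed(config$seed, {
    base <- runif(config$n_items, 2, 9)
    grid <- tidyr::expand_grid(item = items, country = config$countries)
    latent <- clip(base[match(grid$item, items)] + rnorm(nrow(grid), 0, 0.5),
                   1, 10)
    z <- (latent - mean(latent)) / sqrt(mean((latent - mean(latent))^2))
    p_settled <- plogis(config$mixing_effect * z)
    settled <- rbinom(nrow(grid), 1, p_settled) == 1
    tibble::tibble(
      item = grid$item,
      country = grid$country,
      latent_sensitivity = latent,
      sensitivity_z_true = z,
      regime = ifelse(settled, config$settled$regime,
                      config$alternative$regime),
      settled = settled,
      intercept_span = ifelse(settled,
        diff(range(config$settled$cohort_intercepts)),
        diff(range(config$alternative$cohort_intercepts))),
      slope = ifelse(settled,
        config$settled$within_cohort_slopes[1],
        config$alternative$within_cohort_slopes[1])
    )
  })

  # per-pair opinion seeds derived deterministically from the study seed,
  # kept under 2^31
  pair_seed <- (config$seed * 1000L + seq_len(nrow(truth))) %% .Machine$integer.max
  opinions <- dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
    cfg <- if (truth$settled[i]) config$settled else config$alternative
    generate_opinion_data(cfg, country = truth$country[i],
                          item = truth$item[i], seed = pair_seed[i])
  }))

  survey_cfg <- sensitivity_survey_config(
    latent_sensitivity = tibble::tibble(
      country = truth$country, item = truth$item,
      latent = truth$latent_sensitivity
    ),
    n_respondents_per_country = config$n_respondents_per_country,
    rating_noise_sd = config$rating_noise_sd,
    n_attention_checks = config$n_attention_checks,
    p_miss_check = config$p_miss_check
  )
  ratings <- generate_sensitivity_survey(survey_cfg, seed = config$seed + 1L)

  list(opinions = opinions, ratings = ratings, truth = truth)
}
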