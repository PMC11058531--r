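#' Fit the cohort-only opinion model
#'
#' OLS of response on cohort indicators: one mean per birth cohort, no time
#' terms. This is the settled-dispositions benchmark — if beliefs never change
#' after socialisation, year of birth is all you need to predict an opinion.
#'
#' @param data tibble with a `response` column.
#' @param cohort factor of cohort labels aligned with `data` (e.g. from
#'   [assign_cohorts()]), or a `cohort_assignment` object.
#'
#' @return list with `r2`, `fitted`, `n_cohorts`, and the `lm` fit (`model`,
#'   `NULL` for the degenerate single-cohort case).
#' @export
fit_cohort_model <- function(data, cohort) {
  if (inherits(cohort, "cohort_assignment")) cohort <- cohort$cohort
  data <- tibble::as_tibble(data)
  assert_columns(data, "response")
  y <- data$response
  if (length(y) != length(cohort)) {
    stop_config("cohort assignment length (%d) does not match data rows (%d)",
                length(cohort), length(y))
  }
  if (var(y) == 0) stop_config("degenerate outcome: response has zero variance")
  cohort <- droplevels(as.factor(cohort))
  if (nlevels(cohort) < 2) {
    warning("only one cohort present: cohort-only model reduces to the grand mean (R^2 = 0)",
            call. = FALSE)
    return(list(r2 = 0, fitted = rep(mean(y), length(y)),
                n_cohorts = 1L, model = NULL))
  }
  fit <- lm(y ~ cohort)
  list(r2 = r_squared(fit, y), fitted = unname(fitted(fit)),
       n_cohorts = nlevels(cohort), model = fit)
}

#' Fit the cohort + linear-year opinion model
#'
#' Adds to the cohort-only model a linear year term and a cohort-by-year
#' interaction, so every cohort follows its own linear-in-time trend (within-
#' cohort change from age or period effects, pooled). Year is centred at the
#' midpoint of the observed survey years; fitted values and R-squared are
#' invariant to that centring. Cohorts observed in a single year yield an
#' inestimable (aliased) trend; those interaction columns are dropped with a
#' warning.
#'
#' @inheritParams fit_cohort_model
#' @return list with `r2`, `fitted`, `n_cohorts`, `n_dropped_terms`, `model`.
#' @export
fit_cohort_year_model <- function(data, cohort) {
  if (inherits(cohort, "cohort_assignment")) cohort <- cohort$cohort
  data <- tibble::as_tibble(data)
  assert_columns(data, c("response", "survey_year"))
  y <- data$response
  if (length(y) != length(cohort)) {
    stop_config("cohort assignment length (%d) does not match data rows (%d)",
                length(cohort), length(y))
  }
  if (var(y) == 0) stop_config("degenerate outcome: response has zero variance")
  yrs <- unique(data$survey_year)
  if (length(yrs) < 2) {
    stop_config("single survey year: within-cohort trends are not estimable; fit the cohort-only model instead")
  }
  cohort <- droplevels(as.factor(cohort))
  year_c <- data$survey_year - (min(yrs) + max(yrs)) / 2
  fit <- if (nlevels(cohort) < 2) {
    lm(y ~ year_c)
  } else {
    lm(y ~ cohort * year_c)
  }
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    warning(sprintf("dropped %d inestimable term(s) (cohort observed in a single year): %s",
                    sum(aliased),
                    paste(names(coef(fit))[aliased], collapse = ", ")),
            call. = FALSE)
  }
  list(r2 = r_squared(fit, y), fitted = unname(fitted(fit)),
       n_cohorts = nlevels(cohort), n_dropped_terms = sum(aliased),
       model = fit)
}

# Plain OLS coefficient of determination on the estimation sample.
r_squared <- function(fit, y) {
  1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Compute tau, the share of explainable linear change preserved by cohort
#' replacement alone
#'
#' Fits the cohort-only model and the cohort + linear-year model to the same
#' records and returns `tau = R2_cohort_only / R2_full`. Values near 1 mean
#' within-cohort change adds essentially nothing: aggregate change is cohort
#' replacement. Values near 0 mean nearly all explainable linear change is
#' within cohorts. When the full model explains less than `eps` of the
#' variance there is no linear structure to decompose and tau is flagged
#' undefined (`NA`) rather than forced to a number.
#'
#' Cohorts with fewer than `min_per_cohort` observations are merged into their
#' nearest neighbour before fitting (see [assign_cohorts()] for the binning).
#'
#' @param data tibble with columns `response`, `survey_year`, `birth_year`
#'   (plus optional `item`, `country` carried into the result).
#' @param bin_width_years cohort bin width in birth years.
#' @param origin_year optional bin-grid anchor (default: earliest birth year
#'   rounded down to a multiple of the width).
#' @param min_per_cohort minimum observations per cohort before merging.
#' @param eps threshold on the full-model R-squared below which tau is
#'   undefined.
#' @param adjusted use adjusted R-squared in the ratio (default `FALSE`:
#'   plain variance explained).
#'
#' @return one-row tibble: `item`, `country`, `r2_cohort_only`, `r2_full`,
#'   `tau`, `tau_defined`, `n_obs`, `n_cohorts_used`, `bin_width`.
#' @export
#' @examples
#' op <- generate_opinion_data(regime_config("settled"), seed = 1)
#' compute_tau(op)
compute_tau <- function(data, bin_width_years = 5, origin_year = NULL,
                        min_per_cohort = 5, eps = 1e-6, adjusted = FALSE) {
  data <- tibble::as_tibble(data)
  assert_columns(data, c("response", "survey_year", "birth_year"))
  assignment <- assign_cohorts(data$birth_year, bin_width_years, origin_year)
  cohort <- merge_sparse_cohorts(assignment$cohort, min_n = min_per_cohort)

  m1 <- fit_cohort_model(data, cohort)
  m2 <- fit_cohort_year_model(data, cohort)
  r2_1 <- m1$r2
  r2_2 <- m2$r2
  if (adjusted) {
    n <- nrow(data)
    p1 <- if (is.null(m1$model)) 1L else length(coef(m1$model)) - sum(is.na(coef(m1$model)))
    p2 <- length(coef(m2$model)) - sum(is.na(coef(m2$model)))
    r2_1 <- 1 - (1 - r2_1) * (n - 1) / (n - p1)
    r2_2 <- 1 - (1 - r2_2) * (n - 1) / (n - p2)
  }
  defined <- r2_2 >= eps
  tau <- if (defined) min(r2_1 / r2_2, 1) else NA_real_

  tibble::tibble(
    item = single_or_na(column_or_null(data, "item")),
    country = single_or_na(column_or_null(data, "country")),
    r2_cohort_only = r2_1,
    r2_full = r2_2,
    tau = tau,
    tau_defined = defined,
    n_obs = nrow(data),
    n_cohorts_used = m2$n_cohorts,
    bin_width = as.integer(bin_width_years)
  )
}

single_or_na <- function(x) {
  if (is.null(x)) return(NA_character_)
  u <- unique(x)
  if (length(u) == 1) as.character(u) else NA_character_
}

column_or_null <- function(data, col) {
  if (col %in% names(data)) data[[col]] else NULL
}

#' Absolute aggregate change in pooled-SD units
#'
#' The absolute difference between the mean response in the last and first
#' survey waves, divided by the sample SD of the concatenated first- and
#' last-wave responses. A scale-free effect size: invariant under any affine
#' rescaling of the response scale.
#'
#' @param data tibble with columns `response`, `survey_year` (plus optional
#'   `item`, `country`).
#' @return one-row tibble: `item`, `country`, `abs_change_sd`, `first_year`,
#'   `last_year`.
#' @export
#' @examples
#' compute_abs_change(tibble::tibble(
#'   survey_year = rep(c(1981, 2020), each = 4),
#'   response = c(1, 1, 3, 3, 3, 3, 5, 5)))
compute_abs_change <- function(data) {
  data <- tibble::as_tibble(data)
  assert_columns(data, c("response", "survey_year"))
  yrs <- sort(unique(data$survey_year))
  if (length(yrs) < 2) {
    stop_config("at least two distinct survey years are required to measure change")
  }
  first <- data$response[data$survey_year == yrs[1]]
  last <- data$response[data$survey_year == yrs[length(yrs)]]
  pooled_sd <- sd(c(first, last))
  if (pooled_sd == 0) {
    stop_config("degenerate outcome: pooled first+last wave SD is zero")
  }
  tibble::tibble(
    item = single_or_na(column_or_null(data, "item")),
    country = single_or_na(column_or_null(data, "country")),
    abs_change_sd = abs(mean(last) - mean(first)) / pooled_sd,
    first_year = as.integer(yrs[1]),
    last_year = as.integer(yrs[length(yrs)])
  )
}

#' Summarise tau and absolute change for every item and country
#'
#' Applies [compute_tau()] and [compute_abs_change()] to each item-country
#' group of a long-format opinion table. Groups whose fits fail (e.g. a
#' degenerate outcome) are dropped with a warning naming the group; rows with
#' undefined tau are retained and flagged. `label` marks items whose
#' directional change exceeds `label_threshold` pooled SDs, the convention
#' used for annotating the tau-versus-change scatter.
#'
#' @param opinions long tibble with columns `country`, `survey_year`,
#'   `birth_year`, `item`, `response`.
#' @inheritParams compute_tau
#' @param label_threshold absolute change (in pooled SDs) above which an item
#'   is flagged for plot labelling (default 0.8).
#' @param quiet suppress per-group sparse-cohort merge warnings (default
#'   `TRUE`; merges are still counted in the `n_merge_warnings` attribute).
#'
#' @return tibble with one row per item-country: the [compute_tau()] and
#'   [compute_abs_change()] columns plus `label`.
#' @export
summarise_items <- function(opinions, bin_width_years = 5,
                            min_per_cohort = 5, eps = 1e-6,
                            adjusted = FALSE, label_threshold = 0.8,
                            quiet = TRUE) {
  opinions <- tibble::as_tibble(opinions)
  assert_columns(opinions,
                 c("country", "survey_year", "birth_year", "item", "response"),
                 "opinion table")
  groups <- dplyr::group_split(dplyr::group_by(opinions, .data$item,
                                               .data$country))
  n_warn <- 0L
  rows <- lapply(groups, function(g) {
    res <- tryCatch(
      withCallingHandlers(
        {
          tau <- compute_tau(g, bin_width_years = bin_width_years,
                             min_per_cohort = min_per_cohort, eps = eps,
                             adjusted = adjusted)
          chg <- compute_abs_change(g)
          dplyr::bind_cols(tau,
                           chg[, c("abs_change_sd", "first_year", "last_year")])
        },
        warning = function(w) {
          n_warn <<- n_warn + 1L
          if (quiet) invokeRestart("muffleWarning")
        }
      ),
      error = function(e) {
        warning(sprintf("skipping item '%s' in %s: %s",
                        g$item[1], g$country[1], conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$label <- !is.na(out$abs_change_sd) & out$abs_change_sd > label_threshold
  }
  attr(out, "n_merge_warnings") <- n_warn
  out
}
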