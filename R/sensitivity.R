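#' Exclude inattentive respondents
#'
#' Retains exactly the respondents who missed at most `max_missed` attention
#' checks (default 2, i.e. "more than two" misses are excluded). Idempotent.
#'
#' @param ratings tibble of rating records with columns `respondent_id`,
#'   `n_checks_missed`.
#' @param max_missed maximum tolerated misses (>= 0).
#' @param quiet suppress the before/after count message.
#'
#' @return the filtered tibble.
#' @export
apply_attention_filter <- function(ratings, max_missed = 2, quiet = FALSE) {
  ratings <- tibble::as_tibble(ratings)
  assert_columns(ratings, c("respondent_id", "n_checks_missed"),
                 "rating table")
  if (max_missed < 0) stop_config("max_missed must be >= 0")
  n_before <- dplyr::n_distinct(ratings$respondent_id)
  out <- dplyr::filter(ratings, .data$n_checks_missed <= max_missed)
  n_after <- dplyr::n_distinct(out$respondent_id)
  if (!quiet) {
    message(sprintf("attention filter: %d of %d respondents retained (<= %d missed checks)",
                    n_after, n_before, max_missed))
  }
  out
}

#' Aggregate ratings into per-item, per-country sensitivity scores
#'
#' The headline score is the median rating (robust to extreme raters); the
#' mean is kept alongside as a robustness alternative. Items with no retained
#' raters in a country are simply absent from the output.
#'
#' @param ratings tibble with columns `country`, `item`, `rating`
#'   (typically after [apply_attention_filter()]).
#'
#' @return tibble with `item`, `country`, `n_raters`, `median_rating`,
#'   `mean_rating`.
#' @export
aggregate_item_sensitivity <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  assert_columns(ratings, c("country", "item", "rating"), "rating table")
  if (nrow(ratings) == 0) stop_config("no ratings to aggregate")
  dplyr::summarise(
    dplyr::group_by(ratings, .data$item, .data$country),
    n_raters = dplyr::n(),
    median_rating = median(.data$rating),
    mean_rating = mean(.data$rating),
    .groups = "drop"
  )
}

#' Standardise sensitivity scores for use as a model predictor
#'
#' Adds `sensitivity_z = (median_rating - pool mean) / pool SD`, where the
#' pool SD is the population SD (denominator n), so the scores have mean 0
#' and SD exactly 1 over the pool. The pool is global by default (all
#' item-country medians share one scale, so cross-country models compare like
#' with like); `per_country` standardises within each country instead. The
#' downstream prediction grid of -1.5 to +1.5 is expressed in these units.
#'
#' @param items tibble from [aggregate_item_sensitivity()].
#' @param pool `"global"` or `"per_country"`.
#' @param use_mean standardise the mean rating instead of the median.
#'
#' @return `items` with a `sensitivity_z` column added.
#' @export
standardise_sensitivity <- function(items, pool = c("global", "per_country"),
                                    use_mean = FALSE) {
  pool <- match.arg(pool)
  items <- tibble::as_tibble(items)
  assert_columns(items, c("item", "country", "median_rating", "mean_rating"),
                 "sensitivity table")
  score <- if (use_mean) items$mean_rating else items$median_rating
  zfun <- function(x) {
    if (length(x) < 2) stop_config("fewer than 2 items in a standardisation pool")
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop_config("zero SD in a standardisation pool: sensitivity is constant")
    (x - mean(x)) / s
  }
  items$sensitivity_z <- if (pool == "global") {
    zfun(score)
  } else {
    stats::ave(score, items$country, FUN = zfun)
  }
  items
}

#' Most sensitive items per country
#'
#' The top `n` items per country by median rating (ties broken by mean, then
#' item id), the usual descriptive presentation of a sensitivity survey.
#'
#' @param items tibble from [aggregate_item_sensitivity()].
#' @param n items per country.
#' @return tibble sorted within country by descending median.
#' @export
top_sensitive_items <- function(items, n = 3) {
  items <- tibble::as_tibble(items)
  assert_columns(items, c("item", "country", "median_rating", "mean_rating"),
                 "sensitivity table")
  dplyr::slice_head(
    dplyr::arrange(dplyr::group_by(items, .data$country),
                   dplyr::desc(.data$median_rating),
                   dplyr::desc(.data$mean_rating), .data$item),
    n = n
  ) |> dplyr::ungroup()
}

#' Join the tau/change summary with sensitivity scores
#'
#' Inner join on item and country; rows missing from either side are dropped
#' with a message. This is the modelling table consumed by
#' [fit_change_model()] and [fit_tau_mixture_model()].
#'
#' @param tau_tbl output of [summarise_items()].
#' @param sens_tbl output of [standardise_sensitivity()].
#' @return joined tibble.
#' @export
join_tau_sensitivity <- function(tau_tbl, sens_tbl) {
  assert_columns(tau_tbl, c("item", "country"), "tau summary")
  assert_columns(sens_tbl, c("item", "country", "sensitivity_z"),
                 "sensitivity summary")
  out <- dplyr::inner_join(tibble::as_tibble(tau_tbl),
                           tibble::as_tibble(sens_tbl),
                           by = c("item", "country"))
  dropped <- nrow(tau_tbl) - nrow(out)
  if (dropped > 0) {
    message(sprintf("join: %d item-country row(s) lacked a sensitivity score and were dropped",
                    dropped))
  }
  out
}
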