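#' Configure a full study run
#'
#' Bundles every choice a run depends on: input mode (synthetic generation or
#' CSV files), cohort binning, the undefined-tau threshold, sampler settings,
#' which models to fit, and an output directory. The configuration is fully
#' serialisable; [run_study()] echoes it into the output bundle.
#'
#' @param mode `"synthetic"` (generate from `joint`) or `"csv"` (read
#'   `opinion_csv` and `rating_csv`).
#' @param joint a [joint_study_config()] (synthetic mode).
#' @param opinion_csv,rating_csv input paths (csv mode).
#' @param bin_width_years,min_per_cohort,eps,label_threshold passed to
#'   [summarise_items()].
#' @param max_missed attention-check tolerance for [apply_attention_filter()].
#' @param pool standardisation pool for [standardise_sensitivity()].
#' @param models character subset of
#'   `c("change", "mixture", "gaussian")`.
#' @param settings a [sampler_settings()].
#' @param out_dir optional output directory for the bundle files.
#' @param seed integer seed for the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"),
                       joint = joint_study_config(),
                       opinion_csv = NULL, rating_csv = NULL,
                       bin_width_years = 5, min_per_cohort = 5,
                       eps = 1e-6, label_threshold = 0.8,
                       max_missed = 2, pool = "global",
                       models = c("change", "mixture", "gaussian"),
                       settings = sampler_settings(),
                       out_dir = NULL, seed = 1) {
  mode <- match.arg(mode)
  # an empty model set is allowed: summarise without fitting
  if (length(models) > 0) {
    models <- match.arg(models, c("change", "mixture", "gaussian"),
                        several.ok = TRUE)
  }
  if (mode == "csv" && (is.null(opinion_csv) || is.null(rating_csv))) {
    stop_config("csv mode requires opinion_csv and rating_csv paths")
  }
  structure(
    list(mode = mode, joint = joint, opinion_csv = opinion_csv,
         rating_csv = rating_csv, bin_width_years = bin_width_years,
         min_per_cohort = min_per_cohort, eps = eps,
         label_threshold = label_threshold, max_missed = max_missed,
         pool = pool, models = models, settings = settings,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a long-format opinion CSV
#'
#' Expects the header `country,survey_year,birth_year,item,response`; a
#' missing column raises an error naming it.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_opinion_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, c("country", "survey_year", "birth_year", "item",
                       "response"), sprintf("opinion CSV '%s'", path))
  df
}

#' Read a sensitivity-rating CSV
#'
#' Expects the header `respondent_id,country,item,rating,n_checks_missed`.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_rating_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, c("respondent_id", "country", "item", "rating",
                       "n_checks_missed"), sprintf("rating CSV '%s'", path))
  df
}

#' Run the full study pipeline
#'
#' Orchestrates generate (or load) -> summarise -> model -> report:
#' \enumerate{
#'   \item obtain the opinion and rating tables (synthetic generation or CSV);
#'   \item compute tau and absolute change per item and country
#'     ([summarise_items()]);
#'   \item filter inattentive raters, aggregate and standardise sensitivity;
#'   \item fit the requested hierarchical models and their prediction curves;
#'   \item optionally write the bundle: `opinion_data.csv`, `rating_data.csv`,
#'     `tau_summary.csv`, `sensitivity_summary.csv`,
#'     `posterior_summary_<model>.csv`, `prediction_curves_<model>.csv`,
#'     `diagnostics.json`, `run_config.json`, and the figures.
#' }
#' Two runs with the same configuration and seed produce identical CSV
#' outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with `opinions`, `ratings`, `truth` (synthetic
#'   mode), `tau_summary`, `sensitivity_summary`, `model_data`, `fits`
#'   (named list of `ctau_fit`), `curves`, `converged` (all convergence gates
#'   passed), and `status` (0 on success, 2 on a convergence-gate failure).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    study <- generate_joint_study(config$joint)
    opinions <- study$opinions
    ratings <- study$ratings
    truth <- study$truth
  } else {
    opinions <- read_opinion_csv(config$opinion_csv)
    ratings <- read_rating_csv(config$rating_csv)
    truth <- NULL
  }

  message(sprintf("summarising %d item-country group(s)...",
                  dplyr::n_distinct(opinions[, c("item", "country")])))
  tau_summary <- summarise_items(
    opinions, bin_width_years = config$bin_width_years,
    min_per_cohort = config$min_per_cohort, eps = config$eps,
    label_threshold = config$label_threshold
  )
  n_undef <- sum(!tau_summary$tau_defined)
  if (n_undef > 0) {
    message(sprintf("%d item-country row(s) have undefined tau (r2_full < %g)",
                    n_undef, config$eps))
  }

  filtered <- apply_attention_filter(ratings, max_missed = config$max_missed)
  sens <- standardise_sensitivity(aggregate_item_sensitivity(filtered),
                                  pool = config$pool)
  model_data <- join_tau_sensitivity(tau_summary, sens)

  fits <- list()
  st <- config$settings
  if ("change" %in% config$models) {
    message("fitting lognormal change model...")
    fits$change <- fit_change_model(model_data, settings = st)
  }
  if ("mixture" %in% config$models) {
    message("fitting beta-mixture tau model...")
    fits$mixture <- fit_tau_mixture_model(model_data, settings = st)
  }
  if ("gaussian" %in% config$models) {
    message("fitting gaussian tau model...")
    fits$gaussian <- fit_tau_gaussian_model(model_data, settings = st)
  }
  curves <- dplyr::bind_rows(lapply(fits, function(f) f$curves))
  converged <- all(vapply(fits, function(f) f$converged, logical(1)))

  result <- list(opinions = opinions, ratings = ratings, truth = truth,
                 tau_summary = tau_summary, sensitivity_summary = sens,
                 model_data = model_data, fits = fits, curves = curves,
                 converged = converged,
                 status = if (converged) 0L else 2L)

  if (!is.null(config$out_dir)) {
    write_bundle(result, config)
  }
  if (!converged) {
    warning("one or more models failed the convergence gate (status 2)",
            call. = FALSE)
  }
  invisible(result)
}

write_bundle <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  readr::write_csv(result$opinions, out("opinion_data.csv"))
  readr::write_csv(result$ratings, out("rating_data.csv"))
  if (!is.null(result$truth)) {
    readr::write_csv(result$truth, out("truth_table.csv"))
  }
  readr::write_csv(result$tau_summary, out("tau_summary.csv"))
  readr::write_csv(result$sensitivity_summary, out("sensitivity_summary.csv"))
  for (nm in names(result$fits)) {
    fit <- result$fits[[nm]]
    readr::write_csv(fit$summary, out(sprintf("posterior_summary_%s.csv", nm)))
    readr::write_csv(fit$curves, out(sprintf("prediction_curves_%s.csv", nm)))
  }
  diagnostics <- lapply(result$fits, function(f) {
    list(model = f$model, max_rhat = f$max_rhat, converged = f$converged,
         min_ess = min(f$diagnostics$ess, na.rm = TRUE),
         parameters = f$diagnostics)
  })
  jsonlite::write_json(diagnostics, out("diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg <- config
  cfg$joint$settled <- unclass(cfg$joint$settled)
  cfg$joint$alternative <- unclass(cfg$joint$alternative)
  cfg$joint <- unclass(cfg$joint)
  cfg$settings <- unclass(cfg$settings)
  jsonlite::write_json(unclass(cfg), out("run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  ggplot2::ggsave(out("tau_vs_change.png"),
                  plot_tau_vs_change(result$tau_summary,
                                     label_threshold = config$label_threshold),
                  width = 10, height = 7, dpi = 120)
  if (nrow(result$curves) > 0) {
    ggplot2::ggsave(out("prediction_curves.png"),
                    plot_prediction_curves(result$curves),
                    width = 10, height = 5, dpi = 120)
  }
  invisible(config$out_dir)
}

#' Scatter of tau against absolute change, by country
#'
#' Tau on the y-axis, absolute change (pooled SDs) on the x-axis, one facet
#' per country. Items whose change exceeds `label_threshold` are labelled.
#' The upper-right region holds items that changed a lot through cohort
#' replacement; the lower-right, items that changed a lot within cohorts.
#'
#' @param tau_tbl output of [summarise_items()].
#' @param label_threshold labelling threshold on `abs_change_sd`.
#' @return a ggplot object.
#' @export
plot_tau_vs_change <- function(tau_tbl, label_threshold = 0.8) {
  tau_tbl <- tibble::as_tibble(tau_tbl)
  assert_columns(tau_tbl, c("item", "country", "tau", "abs_change_sd"),
                 "tau summary")
  plot_tbl <- tau_tbl[!is.na(tau_tbl$tau), ]
  empty <- setdiff(unique(tau_tbl$country), unique(plot_tbl$country))
  if (length(empty) > 0) {
    warning(sprintf("omitting empty facet(s): %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  lab <- plot_tbl[plot_tbl$abs_change_sd > label_threshold, ]
  ggplot2::ggplot(plot_tbl,
                  ggplot2::aes(x = .data$abs_change_sd, y = .data$tau)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$item),
                       size = 2.5, vjust = -0.6) +
    ggplot2::facet_wrap(~country) +
    ggplot2::labs(
      x = "absolute change between first and last wave (pooled SDs)",
      y = expression(tau ~ "(variance explained preserved by cohort-only model)")
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Model-implied prediction curves by country
#'
#' One line per country over the standardised sensitivity grid, facetted by
#' model when several models' curves are stacked in the table.
#'
#' @param curves_tbl a curves table from [predict_curves()] (possibly several
#'   models row-bound).
#' @return a ggplot object.
#' @export
plot_prediction_curves <- function(curves_tbl) {
  curves_tbl <- tibble::as_tibble(curves_tbl)
  assert_columns(curves_tbl, c("model", "country", "sensitivity_z",
                               "prediction"), "curves table")
  ggplot2::ggplot(curves_tbl,
                  ggplot2::aes(x = .data$sensitivity_z, y = .data$prediction,
                               colour = .data$country)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~model, scales = "free_y") +
    ggplot2::labs(x = "sensitivity (standardised)",
                  y = "posterior-mean prediction", colour = "country") +
    ggplot2::theme_minimal()
}
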