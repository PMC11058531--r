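test_that("cohort-only model R-squared matches hand arithmetic and limits", {
  # two cohorts, means 2 and 6: SST = 20, within-cohort SSR = 4, R^2 = 0.8
  d <- tibble::tibble(response = c(1, 3, 5, 7))
  cohort <- factor(c("A", "A", "B", "B"))
  fit <- fit_cohort_model(d, cohort)
  expect_equal(fit$r2, 0.8)
  expect_equal(fit$fitted, c(2, 2, 6, 6))

  # perfectly explained
  d2 <- tibble::tibble(response = c(0, 0, 1, 1))
  expect_equal(fit_cohort_model(d2, cohort)$r2, 1)

  # single cohort: grand-mean fit, R^2 = 0, with a warning
  expect_warning(f1 <- fit_cohort_model(d, factor(rep("A", 4))), "one cohort")
  expect_equal(f1$r2, 0)

  expect_error(fit_cohort_model(tibble::tibble(response = rep(2, 4)), cohort),
               "zero variance")
})

test_that("cohort+year model honours exact trends, nesting, and degenerate years", {
  # exact per-cohort linear trends, zero noise: R^2 = 1
  d <- tidyr::expand_grid(cohort = c("A", "B"), survey_year = c(2000, 2010),
                          rep = 1:3)
  d$response <- ifelse(d$cohort == "A", 1 + 0.1 * (d$survey_year - 2005),
                       3 - 0.2 * (d$survey_year - 2005))
  d$response <- d$response + 0  # exact
  fit <- fit_cohort_year_model(d, factor(d$cohort))
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # no year dependence: full model never explains less than cohort-only
  withr::with_seed(4, {
    d2 <- tibble::tibble(
      survey_year = rep(c(2000, 2010), each = 20),
      cohort = factor(sample(c("A", "B"), 40, replace = TRUE)),
      response = rnorm(40) + ifelse(cohort == "A", 0, 1))
  })
  f1 <- fit_cohort_model(d2, d2$cohort)
  f2 <- fit_cohort_year_model(d2, d2$cohort)
  expect_gte(f2$r2, f1$r2 - 1e-12)

  expect_error(
    fit_cohort_year_model(dplyr::mutate(d2, survey_year = 2000), d2$cohort),
    "single survey year")
})

test_that("saturated 2x2 fit equals the between-cell variance share from the oracle", {
  d <- tibble::tibble(cohort = c("A", "A", "B", "B"),
                      survey_year = c(2000, 2010, 2000, 2010),
                      response = c(1, 4, 2, 9))
  fit <- fit_cohort_year_model(d, factor(d$cohort))
  expect_equal(fit$r2, oracle_cohort_year_r2(d, d$cohort), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)  # saturated: one obs per cell
})

test_that("both models match the brute-force normal-equations oracle on random small tables", {
  for (seed in 1:12) {
    d <- random_small_table(seed)
    a <- assign_cohorts(d$birth_year, 5)
    co <- droplevels(a$cohort)
    if (nlevels(co) < 2 || var(d$response) == 0) next
    f1 <- suppressWarnings(fit_cohort_model(d, co))
    f2 <- suppressWarnings(fit_cohort_year_model(d, co))
    expect_equal(f1$r2, oracle_cohort_r2(d, co), tolerance = 1e-10)
    expect_equal(f2$r2, oracle_cohort_year_r2(d, co), tolerance = 1e-10)
  }
})

test_that("tau equals the ratio of nested R-squareds and flags undefined decompositions", {
  op <- generate_opinion_data(regime_config("mixed"), seed = 5)
  tr <- suppressWarnings(compute_tau(op))
  expect_equal(tr$tau, tr$r2_cohort_only / tr$r2_full)
  expect_lte(tr$tau, 1)
  expect_true(tr$tau_defined)

  # pure noise: no linear structure to decompose -> undefined, not zero
  withr::with_seed(9, {
    noise <- tibble::tibble(
      birth_year = rep(1950:1959, 40),
      survey_year = rep(c(1990L, 2000L), each = 200),
      response = rnorm(400))
  })
  tn <- suppressWarnings(compute_tau(noise, eps = 0.5))
  expect_false(tn$tau_defined)
  expect_true(is.na(tn$tau))

  # identical fits: tau exactly 1 (settled, zero noise, analysis bins aligned
  # with the generative cohorts so responses are constant within every bin)
  cfg <- regime_config("settled", noise_sd = 0,
                       cohort_intercepts = seq(-1, 1, length.out = 5),
                       n_per_cohort_wave = 10)
  op_z <- generate_opinion_data(cfg, seed = 1)
  blocks <- cohorttau:::cohort_birth_blocks(cfg)
  tz <- suppressWarnings(compute_tau(op_z, bin_width_years = 10,
                                     origin_year = blocks$birth_start[1]))
  expect_equal(tz$tau, 1)
})

test_that("absolute change matches hand arithmetic and is affine invariant", {
  d <- tibble::tibble(survey_year = rep(c(1981L, 2020L), each = 4),
                      response = c(1, 1, 3, 3, 3, 3, 5, 5))
  res <- compute_abs_change(d)
  expect_equal(res$abs_change_sd, 2 / sd(c(1, 1, 3, 3, 3, 3, 5, 5)))
  expect_equal(res$first_year, 1981L)
  expect_equal(res$last_year, 2020L)

  # identical waves: zero change
  d0 <- tibble::tibble(survey_year = rep(c(1981L, 2020L), each = 3),
                       response = c(1, 2, 3, 1, 2, 3))
  expect_equal(compute_abs_change(d0)$abs_change_sd, 0)

  # affine invariance
  d10 <- dplyr::mutate(d, response = response * 10 + 7)
  expect_equal(compute_abs_change(d10)$abs_change_sd, res$abs_change_sd,
               tolerance = 1e-12)

  expect_error(compute_abs_change(dplyr::mutate(d, survey_year = 1981L)),
               "two distinct survey years")
  expect_error(compute_abs_change(dplyr::mutate(d, response = 5)),
               "pooled.*SD is zero")
})

test_that("summarise_items separates regimes per the generator truth and flags large changes", {
  study <- generate_joint_study(joint_study_config(
    n_items = 12, countries = c("USA", "SWE"), mixing_effect = 2, seed = 31))
  smry <- summarise_items(study$opinions)
  joined <- dplyr::inner_join(smry, study$truth, by = c("item", "country"))
  settled_tau <- joined$tau[joined$settled]
  within_tau <- joined$tau[!joined$settled]
  expect_gt(length(settled_tau), 2)
  expect_gt(length(within_tau), 2)
  wt <- stats::wilcox.test(settled_tau, within_tau, alternative = "greater")
  expect_lt(wt$p.value, 0.001)

  expect_equal(smry$label, smry$abs_change_sd > 0.8)

  # a degenerate group is skipped with a warning, others survive
  bad <- dplyr::bind_rows(
    study$opinions,
    tibble::tibble(country = "USA", survey_year = rep(c(1981L, 2020L), 5),
                   birth_year = 1950L, item = "flat", response = 1))
  expect_warning(s2 <- summarise_items(bad), "skipping item 'flat'")
  expect_false("flat" %in% s2$item)
  expect_setequal(s2$item, smry$item)
})

test_that("tau nesting invariant holds across regimes, seeds, and bin widths", {
  configs <- list(regime_config("settled"), regime_config("mixed"),
                  regime_config("within_only"),
                  regime_config("mixed", staggered_entry = TRUE))
  for (cfg in configs) {
    for (seed in 1:3) {
      op <- generate_opinion_data(cfg, seed = seed)
      for (w in c(5, 10)) {
        tr <- suppressWarnings(compute_tau(op, bin_width_years = w))
        expect_gte(tr$r2_full, tr$r2_cohort_only - 1e-12)
        if (tr$tau_defined) expect_lte(tr$tau, 1)
      }
    }
  }
})

test_that("stronger within-cohort slopes weakly decrease expected tau", {
  slopes <- c(0, 0.01, 0.02, 0.04, 0.08)
  mean_taus <- vapply(slopes, function(sl) {
    cfg <- if (sl == 0) regime_config("settled") else
      regime_config("mixed", cohort_intercepts = seq(-1, 1, length.out = 5),
                    within_cohort_slopes = rep(sl, 5))
    mean(vapply(1:20, function(s) {
      suppressWarnings(compute_tau(generate_opinion_data(cfg, seed = s))$tau)
    }, numeric(1)))
  }, numeric(1))
  # weakly decreasing in slope magnitude (small Monte Carlo slack)
  expect_true(all(diff(mean_taus) < 0.02))
  expect_lt(mean_taus[length(slopes)], mean_taus[1])
})
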