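test_that("regime configurations enforce their invariants", {
  expect_error(regime_config("settled", within_cohort_slopes = rep(0.1, 5)),
               "settled regime")
  expect_error(regime_config("within_only",
                             cohort_intercepts = c(0, 0, 0, 0, 1)),
               "intercepts equal")
  expect_error(regime_config("within_only",
                             within_cohort_slopes = rep(0, 5)),
               "nonzero slope")
  expect_error(regime_config("mixed", cohort_intercepts = c(0, 1)),
               "length")
  expect_error(regime_config("settled", n_waves = 1), "at least two")
  expect_error(regime_config("settled", first_year = 2000, last_year = 2003,
                             n_waves = 8), "do not fit")
  expect_error(regime_config("settled", noise_sd = -1), "noise_sd")
})

test_that("opinion generation is deterministic, correctly sized, and adult-only", {
  cfg <- regime_config("mixed", n_per_cohort_wave = 20)
  a <- generate_opinion_data(cfg, "USA", "item01", seed = 7)
  b <- generate_opinion_data(cfg, "USA", "item01", seed = 7)
  c <- generate_opinion_data(cfg, "USA", "item01", seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_equal(nrow(a), cfg$n_waves * cfg$n_cohorts * cfg$n_per_cohort_wave)
  expect_true(all(a$birth_year < a$survey_year))
  expect_true(all(a$survey_year - a$birth_year >= cfg$min_age))
  expect_equal(length(unique(a$survey_year)), cfg$n_waves)
})

test_that("responses respect declared bounds exactly and discretise rounds", {
  cfg <- regime_config("mixed", noise_sd = 3, response_bounds = c(1, 10),
                       discretise = TRUE, n_per_cohort_wave = 50)
  op <- generate_opinion_data(cfg, seed = 2)
  expect_true(all(op$response >= 1 & op$response <= 10))
  expect_true(all(op$response == round(op$response)))
})

test_that("noiseless limits reproduce the regime means exactly", {
  # settled: every cohort's wave mean equals its intercept, in every wave
  cfg <- regime_config("settled", noise_sd = 0,
                       cohort_intercepts = seq(-1, 1, length.out = 5),
                       n_per_cohort_wave = 5)
  op <- generate_opinion_data(cfg, seed = 1)
  blocks <- cohorttau:::cohort_birth_blocks(cfg)
  gen_cohort <- findInterval(op$birth_year, blocks$birth_start)
  cell <- dplyr::summarise(dplyr::group_by(
    dplyr::mutate(op, gc = gen_cohort), .data$gc, .data$survey_year),
    m = mean(response), .groups = "drop")
  expect_equal(cell$m, cfg$cohort_intercepts[cell$gc], tolerance = 1e-12)

  # within-only: every cohort's mean at year t is slope * (t - reference)
  cfg2 <- regime_config("within_only", noise_sd = 0,
                        within_cohort_slopes = rep(0.1, 5),
                        cohort_intercepts = rep(0, 5), n_per_cohort_wave = 5)
  op2 <- generate_opinion_data(cfg2, seed = 1)
  expect_equal(op2$response, 0.1 * (op2$survey_year - reference_year(cfg2)),
               tolerance = 1e-12)
})

test_that("mixed-regime empirical cell means sit within 3 SEs of their generative values", {
  cfg <- regime_config("mixed", cohort_intercepts = seq(-0.5, 0.5, length.out = 5),
                       within_cohort_slopes = rep(0.05, 5), noise_sd = 1,
                       n_per_cohort_wave = 100)
  op <- generate_opinion_data(cfg, seed = 1)
  blocks <- cohorttau:::cohort_birth_blocks(cfg)
  gc <- findInterval(op$birth_year, blocks$birth_start)
  truth <- cfg$cohort_intercepts[gc] +
    cfg$within_cohort_slopes[gc] * (op$survey_year - reference_year(cfg))
  cells <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(gc = gc, year = op$survey_year,
                                   resp = op$response, mu = truth),
                    .data$gc, .data$year),
    err = abs(mean(resp) - mu[1]), n = dplyr::n(), .groups = "drop")
  se <- cfg$noise_sd / sqrt(cells$n)
  # allow a single 3-SE excursion among the 40 cells
  expect_lte(sum(cells$err > 3 * se), 1)
})

test_that("settled aggregate mean equals the cohort-share-weighted intercept mean and drifts under staggered entry", {
  cfg <- regime_config("settled", noise_sd = 0,
                       cohort_intercepts = seq(-1, 1, length.out = 5),
                       n_per_cohort_wave = 10, staggered_entry = TRUE)
  op <- generate_opinion_data(cfg, seed = 3)
  blocks <- cohorttau:::cohort_birth_blocks(cfg)
  agg <- dplyr::summarise(dplyr::group_by(op, .data$survey_year),
                          m = mean(response), .groups = "drop")
  expected <- vapply(agg$survey_year, function(y) {
    alive <- blocks$birth_end + cfg$min_age <= y
    mean(cfg$cohort_intercepts[alive])
  }, numeric(1))
  expect_equal(agg$m, expected, tolerance = 1e-12)
  # composition shifts toward younger (higher-intercept) cohorts over time
  expect_true(all(diff(agg$m) >= 0))
  expect_gt(agg$m[nrow(agg)], agg$m[1])
})

test_that("sensitivity survey honours its noiseless and degenerate limits", {
  lat <- tibble::tibble(country = "USA", item = c("a", "b"),
                        latent = c(2.4, 8.6))
  cfg <- sensitivity_survey_config(lat, n_respondents_per_country = 10,
                                   rating_noise_sd = 0, p_miss_check = 0)
  rt <- generate_sensitivity_survey(cfg, seed = 1)
  expect_setequal(rt$rating[rt$item == "a"], 2L)
  expect_setequal(rt$rating[rt$item == "b"], 9L)
  expect_true(all(rt$n_checks_missed == 0L))
  expect_error(sensitivity_survey_config(lat[0, ]), "at least one item")
  expect_error(sensitivity_survey_config(dplyr::mutate(lat, latent = 12)),
               "1-10")
})

test_that("per-item median ratings recover the latent ordering under noise", {
  lat <- tibble::tibble(country = "USA", item = c("lo", "hi"),
                        latent = c(2, 9))
  cfg <- sensitivity_survey_config(lat, n_respondents_per_country = 200,
                                   rating_noise_sd = 1)
  rt <- generate_sensitivity_survey(cfg, seed = 7)
  med <- tapply(rt$rating, rt$item, median)
  expect_lt(med[["lo"]], med[["hi"]])
  expect_true(all(rt$rating >= 1 & rt$rating <= 10))
})

test_that("joint study couples regime to sensitivity as configured", {
  # positive coupling: items above mean sensitivity settled more often
  study <- generate_joint_study(joint_study_config(
    n_items = 56, mixing_effect = 2, seed = 21))
  tr <- study$truth
  above <- mean(tr$settled[tr$sensitivity_z_true > 0])
  below <- mean(tr$settled[tr$sensitivity_z_true <= 0])
  expect_gt(above, below)

  # zero coupling: regime independent of sensitivity
  null_study <- generate_joint_study(joint_study_config(
    n_items = 56, mixing_effect = 0, seed = 22))
  tn <- null_study$truth
  chisq <- suppressWarnings(
    stats::chisq.test(table(tn$settled, tn$sensitivity_z_true > 0)))
  expect_gt(chisq$p.value, 0.01)

  # determinism of the whole bundle
  again <- generate_joint_study(joint_study_config(
    n_items = 56, mixing_effect = 2, seed = 21))
  expect_identical(study$opinions, again$opinions)
  expect_identical(study$ratings, again$ratings)
  expect_identical(study$truth, again$truth)
})
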