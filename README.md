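# cohorttau

Does public opinion change because people change their minds, or because
generations are replaced? `cohorttau` answers that question per survey item
and per country from repeated cross-sectional data (WVS-style), and tests
whether the answer depends on how *sensitive* — difficult to discuss — each
issue is. It is aimed at researchers of cultural change working with
repeated cross-sections who want a reproducible, testable pipeline rather
than a one-off analysis script.

## The statistic

For each item × country, two nested OLS models are fitted to individual
responses:

1. **cohort-only** — response regressed on birth-cohort indicators (the
   settled-dispositions benchmark: year of birth is all you need);
2. **cohort + linear year + cohort×year** — every cohort gets its own
   linear-in-time trend (within-cohort change from age or period effects,
   pooled).

With R²₁ and R²₂ their coefficients of determination,

    τ = R²₁ / R²₂  ∈ [0, 1]

is the share of linearly explainable change preserved when within-cohort
change is forced to zero: τ ≈ 1 means cohort replacement accounts for the
item's movement, τ ≈ 0 means cohorts moved together. Items are also scored
by absolute change, |last-wave mean − first-wave mean| / SD of the pooled
first+last waves.

Downstream, respondent ratings of how hard each issue is to discuss (1–10
scale, attention-check exclusions, per-item-country medians, standardised)
feed two hierarchical Bayesian models with country-varying intercepts and
slopes, sampled with JAGS:

* a **lognormal regression** of absolute change on sensitivity;
* a **two-component beta mixture** for τ, with the log-odds of belonging to
  the high-τ component a linear function of sensitivity (ordered component
  means, so no label switching). A Gaussian model of τ serves as the
  robustness check.

A seeded synthetic-data generator emulates cohort-structured opinions under
settled / mixed / within-only regimes plus a sensitivity-rating survey, so
every stage is testable end to end and parameter recovery can be verified
against generated truth.

## Worked example

```r
library(cohorttau)

# a full synthetic study: 56 items x 8 countries, opinions + ratings + truth
study <- generate_joint_study(joint_study_config(mixing_effect = 2, seed = 1))

tau_tbl <- summarise_items(study$opinions)
dplyr::select(tau_tbl, item, country, tau, abs_change_sd) |> head(3)
#> # A tibble: 3 × 4
#>   item   country     tau abs_change_sd
#>   <chr>  <chr>     <dbl>         <dbl>
#> 1 item01 ARG     0.00309       1.41
#> 2 item01 AUS     0.991         0.00632
#> 3 item01 CAN     0.0104        1.43

sens <- study$ratings |>
  apply_attention_filter() |>
  aggregate_item_sensitivity() |>
  standardise_sensitivity()
#> attention filter: 799 of 800 respondents retained (<= 2 missed checks)

fit <- fit_tau_mixture_model(join_tau_sensitivity(tau_tbl, sens),
                             sampler_settings(seed = 1))
fit
#> <ctau_fit: tau_mixture>
#>   448 rows, 8 countries, country-varying effects
#>   4 chains x 8000 iterations; max split-R-hat 1.010 (converged)
#>  parameter     mean       sd     q2.5      q25      q50      q75   q97.5
#>          a -0.13557 0.153115 -0.43232 -0.23948 -0.13349 -0.03264 0.16203
#>          b  1.92456 0.201469  1.52743  1.80130  1.92346  2.05129 2.32896
#>      mu[1]  0.00853 0.000314  0.00793  0.00832  0.00852  0.00873 0.00918
#>      mu[2]  0.99364 0.000242  0.99314  0.99348  0.99364  0.99380 0.99409
posterior_mass_above(fit, "b")
#> [1] 1
```

Reading the output: the two beta components sit at mean τ ≈ 0.009 and
≈ 0.994 — the low mode holds items changing within cohorts, the high mode
items changing by cohort replacement (the idealised regimes of this fixture
are cleanly separated; real survey τ values sit further from the
boundaries) — and the mixing slope `b` ≈ 1.9 (log-odds per SD of
sensitivity) with all posterior mass above zero recovers the positive
sensitivity→settled coupling the generator was given (`mixing_effect = 2`). `plot_tau_vs_change(tau_tbl)` and
`plot_prediction_curves(fit$curves)` draw the standard figures, and
`run_study(run_config(...))` runs the whole pipeline and writes a
CSV/JSON/PNG bundle with the exact configuration echoed alongside.

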