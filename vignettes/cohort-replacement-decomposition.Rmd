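---
title: "Decomposing aggregate opinion change: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing aggregate opinion change: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Repeated cross-sectional surveys such as the World Values Survey measure a
country's opinions at several points in time without following individuals.
Two broad accounts compete to explain why such aggregates move. Under
*settled dispositions*, beliefs crystallise during a formative period and
stay put; aggregates then change only because older birth cohorts are
replaced by younger ones socialised under different conditions. Under
*active updating*, adults keep revising their beliefs, so cohorts drift
together with the times. Age and period effects are deliberately pooled
here: the question is not the full age–period–cohort decomposition (which is
unidentifiable in cross-sections anyway) but how much of the *directional*,
linear change in an item is attributable to between-cohort differences
versus within-cohort movement.

## The tau statistic

For each survey item within each country, two nested OLS models are fitted
to individual responses:

* **Model 1 (cohort-only):** response on birth-cohort indicators — one mean
  per cohort, frozen in time.
* **Model 2 (cohort + linear year):** adds a linear survey-year term and a
  cohort-by-year interaction, so each cohort follows its own linear trend.

With $R^2_1$ and $R^2_2$ the plain coefficients of determination of the two
fits,

$$\tau = \frac{R^2_1}{R^2_2} \in [0, 1].$$

Since Model 2 nests Model 1, $R^2_2 \ge R^2_1$ always. $\tau$ near 1 says
within-cohort change adds essentially nothing: cohort membership already
carries all the linearly explainable structure. $\tau$ near 0 says nearly
all explainable linear change happens within cohorts. Alongside $\tau$, each
item's overall movement is summarised as
$|\bar y_{\text{last wave}} - \bar y_{\text{first wave}}|$ divided by the
sample SD of the pooled first+last wave responses — an affine-invariant
effect size, so rescaling a 1–10 item to 0–100 changes nothing.

Key numerical choices:

* **Cohort bins.** Birth years are binned half-open, default width 5 years,
  origin at the earliest birth year rounded down to a multiple of the width.
  The width is a free parameter reported in the output; results at width 5
  and 10 obey the same invariants.
* **Year centring.** Model 2 centres survey year at the midpoint of the
  observed years. Fitted values and $R^2$ are invariant to centring; it only
  conditions the normal equations better.
* **Sparse cohorts.** Cohorts with fewer than 5 observations are merged into
  their nearest neighbouring bin (warning emitted) to keep the interaction
  model full rank. Cohorts observed in a single survey year have no
  estimable trend; their interaction column is dropped with a warning.
* **Undefined tau.** When $R^2_2 < \varepsilon$ (default $10^{-6}$) there is
  no linear structure to decompose and $\tau$ is flagged undefined (`NA`)
  rather than forced to 0 — an item that never moved is not evidence about
  *how* items move. Undefined rows are excluded from the mixture model and
  retained in the change model; both counts are logged.
* **Plain vs adjusted $R^2$.** The ratio uses the unadjusted $R^2$
  ("variance explained"); an adjusted-$R^2$ variant is available as an
  option but is not the default.

## The sensitivity predictor

Item sensitivity — how difficult an issue is for most of one's compatriots
to discuss — is measured by respondent ratings on a 1–10 scale (1 "not
difficult at all", 10 "extremely difficult"). Respondents who miss more than
two attention checks are excluded. Ratings are aggregated per item and
country by the **median** (robust to extreme raters; the mean is kept as a
robustness column) and standardised to `sensitivity_z` using the
**population SD** of the pool (denominator $n$), so scores have mean 0 and
SD exactly 1 and a two-item pool with medians $\{2, 8\}$ maps to
$\{-1, +1\}$. The pool is global by default — cross-country models then
share one sensitivity scale — with a per-country option. All model
predictions are evaluated on a grid from $-1.5$ to $+1.5$ of these units.

## Hierarchical models

Both inferential models have country-varying intercepts and slopes: the
per-country coefficient pair is bivariate normal around the population pair
$(a, b)$ with SDs $\sigma_{u1}, \sigma_{u2}$ and correlation $\rho$.

**Change model.** Absolute change is positive, so it gets a lognormal
likelihood with log-scale linear predictor
$c_{1,j} + c_{2,j} z$ for country $j$. The headline quantity is the
population slope $b$ on the log scale; prediction curves report
$\mathbb{E}[y] = \exp(\eta + \sigma^2/2)$ per country.

**Tau mixture model.** Across items, $\tau$ is strongly bimodal: a low mode
(items moving within cohorts) and a high mode (cohort-replacement items).
$\tau$ is modelled as a two-component beta mixture in mean–precision form,
with the log-odds of belonging to the *higher*-mean component regressed on
`sensitivity_z` (same country-varying structure). The component means are
ordered by construction — $\mu_1 = \operatorname{logit}^{-1}(m_1)$,
$\mu_2 = \operatorname{logit}^{-1}(m_1 + \delta)$ with $\delta > 0$ — which
removes label switching without post-hoc relabelling. $\tau$ values of
exactly 0 or 1 are moved to $0.5/n$ and $(n-0.5)/n$ before likelihood
evaluation; interior values are untouched. Prediction curves report the
mixture mean $\pi \mu_2 + (1 - \pi)\mu_1$. A Gaussian linear model of
$\tau$ on `sensitivity_z` with the same varying effects serves as the
robustness companion; its slope should agree in sign with the mixing slope.

**Priors** (all overridable): Normal(0, 1) on population coefficients
(outcome and predictor are standardised/log scale), half-Normal(0, 1) on
group SDs and residual SDs, Gamma(2, 0.1) on beta precisions (mean 20),
Uniform(−1, 1) on $\rho$ — the two-dimensional LKJ(1) equivalent. Prior
predictive draws stay inside each outcome's support (checked in the test
suite).

**Computation.** Models are sampled with JAGS (Gibbs/slice sampling) through
`rjags`. Two choices matter and were made deliberately:

* *Centred parameterisation.* Country pairs are drawn directly around
  $(a, b)$, factorised as a marginal for the intercept and a conditional for
  the slope (no covariance inversion, which is unstable at $|\rho| \to 1$).
  With informative per-group likelihoods — hundreds of items per country —
  the non-centred form creates a flat ridge between the population
  coefficients and the mean of the group deviations that Gibbs traverses
  extremely slowly; the centred form resolves it.
* *Run length.* Defaults are 4 chains × (1000 adapt + 2000 warmup + 8000
  retained). The binding constraint is the group-slope SD of the mixture's
  mixing logit, which is weakly informed and mixes slowest; at these
  defaults it clears the convergence gate at the package's reference problem
  size (448 item–country pairs).

**Diagnostics.** Split-R-hat (each chain halved, PSRF over the 2m
half-chains) and effective sample size are reported for every monitored
parameter; the convergence gate is split-R-hat < 1.01. Gibbs sampling has no
divergence diagnostic (that is an HMC concept), so the gate is R-hat and ESS
only. Non-convergence produces a warning and `status = 2` from the pipeline,
never a silent result.

## The synthetic-data generator

The generator exists so the entire pipeline is testable without any survey
download, and doubles as the ground-truth machine for parameter-recovery
tests. It emulates:

* **Cohort-structured opinions** under three idealised regimes — *settled*
  (cohort intercepts spread over $2\times$ the noise SD, zero slopes),
  *within-only* (equal intercepts, common slope $0.05 \cdot \text{noise SD}$
  per year), and *mixed* (intercept spread 1.0, common slope 0.05, noise SD
  1). Responses are Normal around the cohort line, optionally clipped to a
  scale and rounded (`discretise`) for 1–10-style items. The window is
  1981–2020 with 8 waves, 5 cohorts of 10 birth years, 100 respondents per
  cohort-wave — a deliberately scaled-down WVS-like design (country-wave
  $n = 500$) chosen once as the package's reference conditions.
* **Cohort entry.** By default every cohort is of age (18+) from the first
  wave, so the design is balanced and composition is fixed. With
  `staggered_entry = TRUE`, cohorts enter the sample when they come of age
  and the settled regime produces the classic composition-driven aggregate
  drift toward younger cohorts' intercepts. No mortality process is
  modelled.
* **A sensitivity survey**: respondents rate every item,
  $\text{rating} = \text{round}(\text{latent} + \text{Normal noise})$
  clipped to 1–10, with Binomial attention-check misses (defaults: 100
  respondents per country, noise SD 1.5, 4 checks at miss probability
  0.05 — roughly the scale of a real 800-respondent, 8-country online
  panel).
* **A joint study** coupling the two: each of 56 items × 8 countries gets a
  latent sensitivity; the probability its opinion series follows the settled
  regime is $\operatorname{logit}^{-1}(\text{mixing\_effect} \times z)$. The
  emitted truth table (regime, latent sensitivity, generative parameters)
  is what recovery tests compare against.

What the generator does *not* emulate — and hence what passing tests cannot
certify about real survey data: sampling weights and stratification, item
nonresponse, nonlinear or shock-driven within-cohort trajectories,
translation effects, respondent-level links between holding an opinion and
rating its sensitivity, and mortality-driven cohort exit. Tests establish
that the statistics and models recover known structure under the stated
generative assumptions, not that those assumptions hold in any particular
survey.

## Problem sizes used in the test suite

Property-style checks run the three reference regimes over 50 seeds each
(about 150 pairs of OLS fits on 4,000-row tables), the oracle-equivalence
checks compare both models to an SVD least-squares solver on random tables
of at most 20 rows, and the Bayesian recovery fixtures use the reference
scale of 56 items × 8 countries (448 outcomes). Reduced-replication
calibration (20 seeded refits at shorter chain lengths) checks interval
coverage for both hierarchical models; shorter chains widen intervals
slightly, which is conservative for coverage.

## Worked example

```{r example}
library(cohorttau)

study <- generate_joint_study(joint_study_config(mixing_effect = 2, seed = 1))
tau_tbl <- summarise_items(study$opinions)

sens <- study$ratings |>
  apply_attention_filter() |>
  aggregate_item_sensitivity() |>
  standardise_sensitivity()

model_data <- join_tau_sensitivity(tau_tbl, sens)
fit <- fit_tau_mixture_model(model_data, sampler_settings(seed = 1))
fit
posterior_mass_above(fit, "b")
plot_prediction_curves(fit$curves)
```

## Known limitations

* $\tau$ compares *linear* trends only; temporary shocks that leave no
  directional trace are invisible to both models, and an item with rich
  nonlinear dynamics can earn an undefined or misleading $\tau$.
* The statistic is a ratio of $R^2$ values, so it inherits their
  sample-size sensitivity; very small item–country cells give noisy $\tau$.
* The cohort bin width is a genuine researcher degree of freedom; it is
  surfaced in the output metadata rather than hidden.
* With few countries the varying-slope SDs are weakly identified; their
  posteriors lean on the half-Normal prior, and the mixture's group-slope
  SD is the slowest-mixing parameter — watch its R-hat and ESS.
* JAGS's discrete mixture indicators make the mixture likelihood exact but
  preclude marginalised gradient-based sampling; very poorly separated
  components will mix slowly.
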