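#' MCMC sampler settings
#'
#' Defaults: 4 chains, 1000 adaptation iterations, 2000 warmup, 8000 retained
#' sampling iterations per chain — enough for the slowest-mixing group-level
#' SDs of the mixture model to clear the split-R-hat < 1.01 gate at the
#' package's reference problem size. The seed drives every chain's RNG
#' deterministically.
#'
#' @param chains number of chains.
#' @param adapt adaptation iterations.
#' @param warmup burn-in iterations discarded after adaptation.
#' @param iter retained sampling iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed.
#' @return list of class `sampler_settings`.
#' @export
sampler_settings <- function(chains = 4, adapt = 1000, warmup = 2000,
                             iter = 8000, thin = 1, seed = 1) {
  stopifnot(chains >= 1, adapt >= 100, warmup >= 0, iter >= 100, thin >= 1)
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), iter = as.integer(iter),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "sampler_settings")
}

#' Default weakly-informative priors
#'
#' Normal(0, `coef_sd`) on population coefficients (outcome and predictor are
#' on standardised or log scales, so unit scale is weakly informative),
#' half-Normal(0, `sd_scale`) on group SDs and the residual SD,
#' Gamma(`phi_shape`, `phi_rate`) on beta precisions (mean 20 by default),
#' and Uniform(-1, 1) on the country intercept-slope correlation (the
#' two-dimensional LKJ(1) prior).
#'
#' @param coef_sd,sd_scale,sigma_scale,phi_shape,phi_rate prior
#'   hyperparameters.
#' @return named list.
#' @export
default_priors <- function(coef_sd = 1, sd_scale = 1, sigma_scale = 1,
                           phi_shape = 2, phi_rate = 0.1) {
  stopifnot(coef_sd > 0, sd_scale > 0, sigma_scale > 0,
            phi_shape > 0, phi_rate > 0)
  list(coef_sd = coef_sd, sd_scale = sd_scale, sigma_scale = sigma_scale,
       phi_shape = phi_shape, phi_rate = phi_rate)
}

# ---- JAGS model templates -------------------------------------------------
# Country effects use the centred parameterisation: per-country intercept and
# slope (c1[j], c2[j]) are bivariate normal around the population pair
# (a, b), factorised as c1 marginal + c2 | c1 conditional so no 2x2
# covariance inversion is needed (which fails near rho = +-1). Centred
# parameterisation mixes far better under Gibbs when the per-group likelihood
# is informative, which these item-rich fixtures are.

jags_varying_block <- function(p) {
  sprintf(
    "  for (j in 1:J) {
    c1[j] ~ dnorm(a, prec_u1)
    c2[j] ~ dnorm(b + rho * (sd_u2 / sd_u1) * (c1[j] - a), prec_c2)
    u1[j] <- c1[j] - a
    u2[j] <- c2[j] - b
  }
  prec_u1 <- pow(sd_u1, -2)
  prec_c2 <- 1 / (sd_u2 * sd_u2 * (1 - rho * rho) + 1.0E-9)
  sd_u1 ~ dnorm(0, %g) T(0,)
  sd_u2 ~ dnorm(0, %g) T(0,)
  rho ~ dunif(-1, 1)",
    1 / p$sd_scale^2, 1 / p$sd_scale^2)
}

jags_model_string <- function(likelihood, varying, p) {
  coef_prec <- 1 / p$coef_sd^2
  sigma_prec <- 1 / p$sigma_scale^2
  eta <- if (varying) {
    "c1[g[i]] + c2[g[i]] * z[i]"
  } else {
    "a + b * z[i]"
  }
  lik <- switch(likelihood,
    lognormal = sprintf(
      "  for (i in 1:N) {
    y[i] ~ dlnorm(eta[i], tau_y)
    eta[i] <- %s
  }
  sigma ~ dnorm(0, %g) T(0,)
  tau_y <- pow(sigma, -2)", eta, sigma_prec),
    gaussian = sprintf(
      "  for (i in 1:N) {
    y[i] ~ dnorm(eta[i], tau_y)
    eta[i] <- %s
  }
  sigma ~ dnorm(0, %g) T(0,)
  tau_y <- pow(sigma, -2)", eta, sigma_prec),
    beta_mixture = sprintf(
      "  for (i in 1:N) {
    w[i] ~ dbern(p_high[i])
    logit(p_high[i]) <- %s
    k[i] <- w[i] + 1
    y[i] ~ dbeta(mu[k[i]] * phi[k[i]], (1 - mu[k[i]]) * phi[k[i]])
  }
  # ordered component means on the logit scale: mu[1] < mu[2] by construction
  m1 ~ dnorm(0, %g)
  gap ~ dnorm(0, %g) T(0,)
  logit(mu[1]) <- m1
  logit(mu[2]) <- m1 + gap
  phi[1] ~ dgamma(%g, %g)
  phi[2] ~ dgamma(%g, %g)", eta, coef_prec, coef_prec,
      p$phi_shape, p$phi_rate, p$phi_shape, p$phi_rate)
  )
  paste0(
    "model {\n", lik, "\n",
    if (varying) paste0(jags_varying_block(p), "\n") else "",
    sprintf("  a ~ dnorm(0, %g)\n  b ~ dnorm(0, %g)\n}", coef_prec, coef_prec)
  )
}

# ---- runner and diagnostics -----------------------------------------------

run_jags <- function(model_string, data, monitors, settings,
                     extra_inits = NULL) {
  base_seed <- settings$seed %% 21470000L
  inits <- lapply(seq_len(settings$chains), function(k) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = base_seed * 100L + k),
      extra_inits %||% list())
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = settings$chains,
                             n.adapt = settings$adapt, quiet = TRUE)
  if (settings$warmup > 0) {
    stats::update(model, n.iter = settings$warmup, progress.bar = "none")
  }
  rjags::coda.samples(model, variable.names = monitors,
                      n.iter = settings$iter, thin = settings$thin,
                      progress.bar = "none")
}

#' Split-R-hat convergence diagnostic
#'
#' Each chain is split in half and the usual potential-scale-reduction factor
#' is computed over the 2m half-chains, so within-chain drift also inflates
#' the statistic. Values near 1 indicate agreement; the package's convergence
#' gate is split-R-hat < 1.01 on every monitored parameter.
#'
#' @param samples a `coda::mcmc.list`.
#' @return named numeric vector, one value per parameter (`NA` for constant
#'   parameters).
#' @export
split_rhat <- function(samples) {
  chains <- lapply(samples, as.matrix)
  params <- colnames(chains[[1]])
  n <- nrow(chains[[1]])
  n2 <- floor(n / 2)
  vapply(params, function(pp) {
    halves <- do.call(cbind, lapply(chains, function(ch) {
      cbind(ch[seq_len(n2), pp], ch[(n - n2 + 1):n, pp])
    }))
    w <- mean(apply(halves, 2, var))
    if (!is.finite(w) || w == 0) return(NA_real_)
    b <- n2 * var(colMeans(halves))
    sqrt(((n2 - 1) / n2 * w + b / n2) / w)
  }, numeric(1))
}

summarise_draws <- function(samples) {
  draws <- as.matrix(samples)
  qs <- t(apply(draws, 2, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  tibble::tibble(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    q2.5 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3], q75 = qs[, 4],
    q97.5 = qs[, 5]
  )
}

make_fit <- function(model_id, samples, data_used, countries, varying,
                     settings, priors, meta = list()) {
  rhat <- split_rhat(samples)
  ess <- coda::effectiveSize(samples)[names(rhat)]
  diagnostics <- tibble::tibble(
    parameter = names(rhat),
    rhat = unname(rhat),
    ess = unname(ess)
  )
  max_rhat <- suppressWarnings(max(rhat, na.rm = TRUE))
  converged <- is.finite(max_rhat) && max_rhat < 1.01
  if (!converged) {
    warning(sprintf("%s: convergence gate failed (max split-R-hat = %.4f); treat estimates with caution",
                    model_id, max_rhat), call. = FALSE)
  }
  fit <- structure(
    list(model = model_id, samples = samples, draws = as.matrix(samples),
         summary = summarise_draws(samples), diagnostics = diagnostics,
         max_rhat = max_rhat, converged = converged,
         countries = countries, varying = varying, data = data_used,
         settings = settings, priors = priors, meta = meta),
    class = "ctau_fit"
  )
  fit$curves <- predict_curves(fit)
  fit
}

#' @export
print.ctau_fit <- function(x, ...) {
  cat(sprintf("<ctau_fit: %s>\n", x$model))
  cat(sprintf("  %d rows, %d countr%s, %s effects\n", nrow(x$data),
              length(x$countries), if (length(x$countries) == 1) "y" else "ies",
              if (x$varying) "country-varying" else "population-only"))
  cat(sprintf("  %d chains x %d iterations; max split-R-hat %.3f (%s)\n",
              x$settings$chains, x$settings$iter, x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  pop <- x$summary[x$summary$parameter %in%
                     c("a", "b", "sigma", "mu[1]", "mu[2]"), ]
  print(as.data.frame(pop), digits = 3, row.names = FALSE)
  invisible(x)
}

prepare_model_data <- function(data, outcome_col, what) {
  data <- tibble::as_tibble(data)
  assert_columns(data, c(outcome_col, "sensitivity_z", "country"), what)
  keep <- complete.cases(data[, c(outcome_col, "sensitivity_z", "country")])
  if (sum(!keep) > 0) {
    message(sprintf("%s: dropped %d row(s) with missing outcome or predictor",
                    what, sum(!keep)))
  }
  data[keep, ]
}

# ---- model fits -----------------------------------------------------------

#' Hierarchical lognormal regression of absolute change on sensitivity
#'
#' Models pooled-SD absolute change (a strictly positive outcome) as
#' lognormal, with a log-scale linear predictor
#' `a + b * sensitivity_z + u1[country] + u2[country] * sensitivity_z`:
#' population intercept and slope plus country-varying deviations with a
#' correlation between intercept and slope deviations. The population slope
#' `b` (log scale) is the headline coefficient. With a single country the
#' model falls back to population effects only, with a warning.
#'
#' @param data tibble with columns `abs_change_sd` (> 0), `sensitivity_z`,
#'   `country` (e.g. from [join_tau_sensitivity()]).
#' @param settings a [sampler_settings()].
#' @param priors a [default_priors()] list.
#' @return a `ctau_fit`: posterior draws, summary, split-R-hat and effective
#'   sample size per parameter, and per-country prediction curves over the
#'   standardised sensitivity grid.
#' @export
fit_change_model <- function(data, settings = sampler_settings(),
                             priors = default_priors()) {
  data <- prepare_model_data(data, "abs_change_sd", "change model")
  if (any(data$abs_change_sd <= 0)) {
    stop_config("change model: %d outcome(s) are zero or negative; the lognormal likelihood needs strictly positive change — exclude those rows or floor them explicitly before fitting",
                sum(data$abs_change_sd <= 0))
  }
  countries <- sort(unique(data$country))
  varying <- length(countries) >= 2
  if (!varying) {
    warning("single country: fitting population effects only (no varying intercepts/slopes)",
            call. = FALSE)
  }
  jd <- list(N = nrow(data), y = data$abs_change_sd, z = data$sensitivity_z)
  monitors <- c("a", "b", "sigma")
  if (varying) {
    jd$J <- length(countries)
    jd$g <- match(data$country, countries)
    monitors <- c(monitors, "sd_u1", "sd_u2", "rho", "u1", "u2")
  }
  samples <- run_jags(jags_model_string("lognormal", varying, priors),
                      jd, monitors, settings)
  make_fit("change_lognormal", samples, data, countries, varying,
           settings, priors)
}

#' Two-component beta mixture for tau with sensitivity-dependent mixing
#'
#' Tau is bimodal across items: some items change almost entirely through
#' cohort replacement (tau near 1), others mostly within cohorts (tau near
#' 0). The model treats each tau as drawn from one of two beta distributions
#' (mean-precision parameterisation, component means ordered `mu[1] < mu[2]`
#' by construction, which removes label switching), and regresses the
#' log-odds that an item belongs to the *higher*-tau component on its
#' standardised sensitivity, with country-varying intercepts and slopes. The
#' population mixing slope `b` (log-odds scale) is the headline coefficient:
#' positive values mean more sensitive items are more likely to change via
#' cohort replacement.
#'
#' Rows with undefined tau are dropped (counted in `meta`). Tau values of
#' exactly 0 or 1 are moved to `0.5/n` and `(n - 0.5)/n` before likelihood
#' evaluation (n = modelled rows); interior values are untouched.
#'
#' @param data tibble with columns `tau`, `sensitivity_z`, `country` (and
#'   optionally `tau_defined`).
#' @inheritParams fit_change_model
#' @return a `ctau_fit` (see [fit_change_model()]); prediction curves give
#'   the model-implied mean tau `p * mu[2] + (1 - p) * mu[1]`.
#' @export
fit_tau_mixture_model <- function(data, settings = sampler_settings(),
                                  priors = default_priors()) {
  data <- tibble::as_tibble(data)
  if ("tau_defined" %in% names(data)) {
    n_undef <- sum(!data$tau_defined)
    if (n_undef > 0) {
      message(sprintf("tau mixture: dropping %d row(s) with undefined tau (no linear structure to decompose)",
                      n_undef))
      data <- data[data$tau_defined, ]
    }
  }
  data <- prepare_model_data(data, "tau", "tau mixture")
  if (nrow(data) < 20) {
    stop_config("tau mixture: only %d tau values; a two-component mixture is not identifiable at this size — supply at least 20 rows",
                nrow(data))
  }
  if (any(data$tau < 0 | data$tau > 1)) {
    stop_config("tau mixture: tau values outside [0, 1]")
  }
  n <- nrow(data)
  y <- data$tau
  n_boundary <- sum(y == 0 | y == 1)
  y[y == 0] <- 0.5 / n
  y[y == 1] <- (n - 0.5) / n
  data$tau <- y  # the outcome as modelled, boundary-adjusted

  countries <- sort(unique(data$country))
  varying <- length(countries) >= 2
  if (!varying) {
    warning("single country: fitting population effects only (no varying intercepts/slopes)",
            call. = FALSE)
  }
  jd <- list(N = n, y = y, z = data$sensitivity_z)
  monitors <- c("a", "b", "mu", "phi")
  if (varying) {
    jd$J <- length(countries)
    jd$g <- match(data$country, countries)
    monitors <- c(monitors, "sd_u1", "sd_u2", "rho", "u1", "u2")
  }
  # start the components apart and the mixing regression at zero
  extra_inits <- list(m1 = qlogis(0.3), gap = 2, a = 0, b = 0)
  samples <- run_jags(jags_model_string("beta_mixture", varying, priors),
                      jd, monitors, settings, extra_inits = extra_inits)
  make_fit("tau_mixture", samples, data, countries, varying, settings,
           priors, meta = list(n_boundary_adjusted = n_boundary))
}

#' Gaussian robustness model for tau
#'
#' A hierarchical Gaussian linear regression of tau on standardised
#' sensitivity with the same country-varying intercepts and slopes as the
#' mixture model. Used as a robustness check: the sign and credibility of its
#' slope should agree with the mixture model's mixing slope.
#'
#' @inheritParams fit_tau_mixture_model
#' @return a `ctau_fit`.
#' @export
fit_tau_gaussian_model <- function(data, settings = sampler_settings(),
                                   priors = default_priors()) {
  data <- tibble::as_tibble(data)
  if ("tau_defined" %in% names(data)) data <- data[data$tau_defined, ]
  data <- prepare_model_data(data, "tau", "tau gaussian")
  countries <- sort(unique(data$country))
  varying <- length(countries) >= 2
  if (!varying) {
    warning("single country: fitting population effects only (no varying intercepts/slopes)",
            call. = FALSE)
  }
  jd <- list(N = nrow(data), y = data$tau, z = data$sensitivity_z)
  monitors <- c("a", "b", "sigma")
  if (varying) {
    jd$J <- length(countries)
    jd$g <- match(data$country, countries)
    monitors <- c(monitors, "sd_u1", "sd_u2", "rho", "u1", "u2")
  }
  samples <- run_jags(jags_model_string("gaussian", varying, priors),
                      jd, monitors, settings)
  make_fit("tau_gaussian", samples, data, countries, varying, settings,
           priors)
}

#' Model-implied prediction curves over the sensitivity grid
#'
#' For each country and each grid value of standardised sensitivity, the
#' posterior-mean predicted outcome: expected absolute change
#' `exp(eta + sigma^2 / 2)` for the lognormal model, the mixture mean
#' `p * mu[2] + (1 - p) * mu[1]` for the tau mixture, and the linear
#' predictor for the Gaussian model. The default grid spans -1.5 to +1.5
#' standardised units in steps of 0.25.
#'
#' @param fit a `ctau_fit`.
#' @param grid numeric grid of standardised sensitivity values; values beyond
#'   3 SD trigger an extrapolation warning.
#' @return tibble with columns `model`, `country`, `sensitivity_z`,
#'   `prediction`.
#' @export
predict_curves <- function(fit, grid = seq(-1.5, 1.5, by = 0.25)) {
  stopifnot(inherits(fit, "ctau_fit"))
  if (any(abs(grid) > 3)) {
    warning("prediction grid extends beyond 3 SD of sensitivity: extrapolation",
            call. = FALSE)
  }
  draws <- fit$draws
  a <- draws[, "a"]
  b <- draws[, "b"]
  countries <- fit$countries
  rows <- lapply(seq_along(countries), function(j) {
    if (fit$varying) {
      u1 <- draws[, sprintf("u1[%d]", j)]
      u2 <- draws[, sprintf("u2[%d]", j)]
    } else {
      u1 <- 0
      u2 <- 0
    }
    pred <- vapply(grid, function(zv) {
      eta <- a + b * zv + u1 + u2 * zv
      mean(switch(fit$model,
        change_lognormal = exp(eta + draws[, "sigma"]^2 / 2),
        tau_mixture = {
          p <- plogis(eta)
          p * draws[, "mu[2]"] + (1 - p) * draws[, "mu[1]"]
        },
        tau_gaussian = eta
      ))
    }, numeric(1))
    tibble::tibble(model = fit$model, country = countries[j],
                   sensitivity_z = grid, prediction = pred)
  })
  dplyr::bind_rows(rows)
}

#' Posterior mass of a parameter above a threshold
#'
#' @param fit a `ctau_fit`.
#' @param parameter monitored parameter name (default `"b"`, the population
#'   sensitivity slope).
#' @param value threshold (default 0).
#' @return proportion of posterior draws strictly above `value`.
#' @export
posterior_mass_above <- function(fit, parameter = "b", value = 0) {
  stopifnot(inherits(fit, "ctau_fit"))
  if (!parameter %in% colnames(fit$draws)) {
    stop_config("parameter '%s' was not monitored", parameter)
  }
  mean(fit$draws[, parameter] > value)
}

# ---- prior predictive checks ----------------------------------------------

#' Prior predictive draws
#'
#' Simulates outcomes from the priors alone (no data): tau from the beta
#' mixture, absolute change from the lognormal model. Used to check that the
#' priors put mass only on the outcome's support — tau in (0, 1), change in
#' (0, Inf).
#'
#' @param n number of draws.
#' @param model `"tau_mixture"` or `"change_lognormal"`.
#' @param priors a [default_priors()] list.
#' @param seed integer seed.
#' @return numeric vector of simulated outcomes.
#' @export
prior_predictive <- function(n, model = c("tau_mixture", "change_lognormal"),
                             priors = default_priors(), seed = 1) {
  model <- match.arg(model)
  withr::with_seed(seed, {
    z <- rnorm(n)
    a <- rnorm(n, 0, priors$coef_sd)
    b <- rnorm(n, 0, priors$coef_sd)
    eta <- a + b * z
    if (model == "tau_mixture") {
      m1 <- rnorm(n, 0, priors$coef_sd)
      gap <- abs(rnorm(n, 0, priors$coef_sd))
      mu1 <- plogis(m1)
      mu2 <- plogis(m1 + gap)
      phi1 <- rgamma(n, priors$phi_shape, priors$phi_rate)
      phi2 <- rgamma(n, priors$phi_shape, priors$phi_rate)
      w <- rbinom(n, 1, plogis(eta))
      mu <- ifelse(w == 1, mu2, mu1)
      phi <- ifelse(w == 1, phi2, phi1)
      rbeta(n, mu * phi, (1 - mu) * phi)
    } else {
      sigma <- abs(rnorm(n, 0, priors$sigma_scale))
      rlnorm(n, eta, sigma)
    }
  })
}
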