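# Reduced sampler settings for unit-scale checks; acceptance-scale fits use
# their own settings.
fast_settings <- function(seed = 1, chains = 2) {
  sampler_settings(chains = chains, adapt = 300, warmup = 400, iter = 600,
                   seed = seed)
}

# Synthetic tau values from two beta components (mean-precision 0.25/0.85,
# phi 20) with a hierarchical logit-linear mixing probability: the
# parameter-recovery truth for the mixture model. 56 items x 8 countries by
# default.
make_mixture_fixture <- function(seed, slope = 1, n_items = 56, n_countries = 8,
                                 intercept = 0, sd_u1 = 0.3, sd_u2 = 0.2,
                                 mu = c(0.25, 0.85), phi = 20) {
  withr::with_seed(seed, {
    n <- n_items * n_countries
    country <- rep(sprintf("C%02d", seq_len(n_countries)), each = n_items)
    z <- rnorm(n)
    u1 <- rnorm(n_countries, 0, sd_u1)
    u2 <- rnorm(n_countries, 0, sd_u2)
    g <- match(country, unique(country))
    p_high <- plogis(intercept + slope * z + u1[g] + u2[g] * z)
    high <- rbinom(n, 1, p_high) == 1
    m <- ifelse(high, mu[2], mu[1])
    tau <- rbeta(n, m * phi, (1 - m) * phi)
    tibble::tibble(item = rep(sprintf("item%02d", seq_len(n_items)),
                              n_countries),
                   country = country, tau = tau, tau_defined = TRUE,
                   sensitivity_z = z, high = high)
  })
}

# Strictly positive absolute-change outcomes from a lognormal with log-scale
# slope `slope` on standardised sensitivity, at the same 56 x 8 scale.
make_change_fixture <- function(seed, slope = 0.3, n_items = 56,
                                n_countries = 8, intercept = -1.5,
                                sd_u1 = 0.15, sd_u2 = 0.1, sigma = 0.4) {
  withr::with_seed(seed, {
    n <- n_items * n_countries
    country <- rep(sprintf("C%02d", seq_len(n_countries)), each = n_items)
    z <- rnorm(n)
    u1 <- rnorm(n_countries, 0, sd_u1)
    u2 <- rnorm(n_countries, 0, sd_u2)
    g <- match(country, unique(country))
    y <- rlnorm(n, intercept + slope * z + u1[g] + u2[g] * z, sigma)
    tibble::tibble(item = rep(sprintf("item%02d", seq_len(n_items)),
                              n_countries),
                   country = country, abs_change_sd = y, sensitivity_z = z)
  })
}

# Mean tau over seeds for a reference regime.
mean_tau_over_seeds <- function(regime, seeds) {
  cfg <- regime_config(regime)
  mean(vapply(seeds, function(s) {
    op <- generate_opinion_data(cfg, seed = s)
    suppressWarnings(compute_tau(op)$tau)
  }, numeric(1)))
}
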