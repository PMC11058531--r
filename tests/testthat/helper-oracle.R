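# Brute-force least-squares oracle: solves the normal equations through the
# SVD pseudo-inverse, independent of lm() and of the package's fit path.
# Handles rank-deficient designs (the projection, hence R^2, is unique).
oracle_r2 <- function(X, y) {
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  fitted <- sv$u[, pos, drop = FALSE] %*%
    crossprod(sv$u[, pos, drop = FALSE], y)
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

oracle_cohort_r2 <- function(data, cohort) {
  X <- model.matrix(~ 0 + factor(cohort))
  oracle_r2(X, data$response)
}

oracle_cohort_year_r2 <- function(data, cohort) {
  yrs <- range(data$survey_year)
  year_c <- data$survey_year - mean(yrs)
  f <- factor(cohort)
  X <- cbind(model.matrix(~ 0 + f), model.matrix(~ 0 + f) * year_c)
  oracle_r2(X, data$response)
}

# Random small opinion tables for oracle-equivalence checks.
random_small_table <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(6:20, 1)
    tibble::tibble(
      birth_year = sample(seq(1940, 1975, by = 5), n, replace = TRUE) +
        sample(0:4, n, replace = TRUE),
      survey_year = sample(c(1990L, 2000L, 2010L), n, replace = TRUE),
      response = rnorm(n)
    )
  })
}
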