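# Independent brute-force oracles used across tests. These deliberately avoid
# the package's own linear-algebra paths: explicit normal equations, explicit
# element loops for the sandwich, and closed-form likelihood expressions.

# weighted least squares by the normal equations
ols_oracle <- function(X, y, w = rep(1, length(y))) {
  drop(solve(t(X) %*% (w * X), t(X) %*% (w * y)))
}

# sandwich covariance assembled element by element with loops
sandwich_oracle <- function(X, e, w = rep(1, nrow(X)), hc1 = TRUE) {
  n <- nrow(X)
  k <- ncol(X)
  A <- matrix(0, k, k)
  for (i in seq_len(n)) {
    A <- A + w[i] * X[i, ] %*% t(X[i, ])
  }
  Ainv <- solve(A)
  M <- matrix(0, k, k)
  for (i in seq_len(n)) {
    M <- M + (w[i] * e[i])^2 * X[i, ] %*% t(X[i, ])
  }
  if (hc1) M <- M * n / (n - k)
  Ainv %*% M %*% Ainv
}

# concentrated Gaussian log-likelihood given a residual sum of squares
concentrated_loglik_oracle <- function(rss, n) {
  -(n / 2) * (1 + log(2 * pi * rss / n))
}

# moment-ratio skewness written out longhand
skewness_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m3 / (m2^(3 / 2))
}

# tiny deterministic PSU fixture with hand-checkable collapsed values
psu_fixture <- function() {
  tibble::tibble(
    psu_id = c("A", "A", "A", "B", "B", "C", "C", "C", "C"),
    od_household = c(1, 1, 0, 0, 0, 1, 1, 1, 0),
    haz = c(-3, -1, -2.5, -0.5, -1.5, -3.5, -2.2, -1.8, -0.5)
  )
}

# generator settings used by several recovery tests: no controls, modest noise
log_linear_params <- function(seed, n = 500, noise_sd = 2) {
  district_sim_params(
    n_districts = n, noise_sd = noise_sd,
    control_effects = c(urban_pct = 0), seed = seed
  )
}
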