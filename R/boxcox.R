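# Box-Cox selection of the exposure transformation. Unlike the textbook
# procedure, the transformation is applied to an *independent* variable, so
# the Gaussian likelihood of the untransformed outcome needs no Jacobian
# term: for each candidate lambda the outcome is regressed on the transformed
# exposure (plus any covariates) and the concentrated log-likelihood
# -(n/2) * (1 + log(2*pi*RSS/n)) is profiled over lambda.

#' Box-Cox power transform
#'
#' `(x^lambda - 1) / lambda`, which tends to `ln(x)` as `lambda -> 0`. Both
#' arguments are vectorized (recycled).
#'
#' @param x Strictly positive values.
#' @param lambda Transformation parameter.
#' @return Transformed values.
#' @examples
#' boxcox_transform(exp(1), 0) # 1
#' boxcox_transform(4, 0.5) # 2
#' @export
boxcox_transform <- function(x, lambda) {
  if (any(x <= 0, na.rm = TRUE)) {
    abort("`x` must be strictly positive for the Box-Cox transform.",
      class = "sanistunt_domain_error"
    )
  }
  n <- max(length(x), length(lambda))
  x <- rep_len(as.numeric(x), n)
  lambda <- rep_len(as.numeric(lambda), n)
  out <- numeric(n)
  zero <- lambda == 0
  out[zero] <- log(x[zero])
  # expm1 keeps the lambda -> 0 limit numerically continuous
  out[!zero] <- expm1(lambda[!zero] * log(x[!zero])) / lambda[!zero]
  out
}

bc_design <- function(data, outcome, exposure, covariates, weights) {
  covariates <- if (is.null(covariates)) list() else as_term_list(covariates)
  cov_cols <- vapply(covariates, `[[`, character(1), "column")
  used <- unique(c(outcome, exposure, cov_cols, weights))
  check_columns(data, used, "model data")
  keep <- complete.cases(data[used])
  data <- data[keep, , drop = FALSE]
  xexp <- as.numeric(data[[exposure]])
  if (any(xexp <= 0)) {
    abort(sprintf("Exposure `%s` must be strictly positive in all rows.", exposure),
      class = "sanistunt_domain_error"
    )
  }
  Z <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (length(covariates) > 0) {
    Zc <- vapply(
      covariates,
      function(t) apply_transform(as.numeric(data[[t$column]]), t),
      numeric(nrow(data))
    )
    Zc <- matrix(Zc, nrow = nrow(data))
    colnames(Zc) <- vapply(covariates, term_label, character(1))
    Z <- cbind(Z, Zc)
  }
  w <- if (is.null(weights)) rep(1, nrow(data)) else as.numeric(data[[weights]])
  if (any(w <= 0)) {
    abort("All weights must be strictly positive.", class = "sanistunt_data_error")
  }
  w <- w * nrow(data) / sum(w)
  list(y = as.numeric(data[[outcome]]), x = xexp, Z = Z, w = w, n = nrow(data))
}

bc_loglik_at <- function(parts, lambda) {
  X <- cbind(parts$Z, bc = boxcox_transform(parts$x, lambda))
  fit <- stats::lm.wfit(X, parts$y, parts$w)
  rss <- sum(parts$w * fit$residuals^2)
  n <- parts$n
  -(n / 2) * (1 + log(2 * pi * rss / n))
}

#' Profile log-likelihood of the exposure transformation
#'
#' Concentrated Gaussian log-likelihood of the outcome regressed on the
#' Box-Cox-transformed exposure (plus covariates), maximized over
#' coefficients and error variance; equal to `-(n/2)(1 + log(2*pi*RSS/n))`
#' where `RSS` is the residual sum of squares at that `lambda`. The outcome
#' is untransformed, so no Jacobian term enters.
#'
#' @param data A data frame.
#' @param outcome Outcome column name.
#' @param exposure Strictly positive exposure column name.
#' @param lambda Transformation parameter(s); vectorized.
#' @param covariates Optional list of [wls_term()]s (or column names) also in
#'   the regression.
#' @param weights Optional analytic-weight column; the default is unweighted.
#' @return A numeric vector of log-likelihoods, one per `lambda`.
#' @export
boxcox_profile_loglik <- function(data, outcome, exposure, lambda,
                                  covariates = NULL, weights = NULL) {
  parts <- bc_design(data, outcome, exposure, covariates, weights)
  vapply(lambda, function(l) bc_loglik_at(parts, l), numeric(1))
}

#' Estimate the Box-Cox transformation of an exposure
#'
#' Profiles the concentrated log-likelihood over a grid, refines the maximum
#' with golden-section search ([stats::optimize()]), and inverts the
#' likelihood-ratio test for the 95% confidence interval: the CI endpoints
#' are the `lambda` values where the profile drops `qchisq(0.95, 1)/2`
#' (about 1.92) below its maximum. LR tests against `lambda = -1, 0, 1` are
#' reported by default. `lambda = 0` is the natural-log transform; the
#' estimate is scale-dependent, so the exposure is used on its native scale
#' (percent, for district data).
#'
#' @inheritParams boxcox_profile_loglik
#' @param bounds Search interval for `lambda` (default `c(-3, 3)`).
#' @param grid_step Spacing of the coarse profile grid (default 0.05).
#' @param lr_null Null values for the reported likelihood-ratio tests.
#' @return A `boxcox_fit` with `lambda_hat`, `ci_95`, a `profile` tibble of
#'   `(lambda, loglik)`, an `lr_tests` tibble, and the maximized
#'   log-likelihood.
#' @examples
#' d <- simulate_districts(district_sim_params(seed = 7))
#' fit <- estimate_boxcox_lambda(d, "stunting_pct", "od_pct")
#' fit
#' @export
estimate_boxcox_lambda <- function(data, outcome, exposure,
                                   covariates = NULL, weights = NULL,
                                   bounds = c(-3, 3), grid_step = 0.05,
                                   lr_null = c(-1, 0, 1)) {
  if (!is.numeric(bounds) || length(bounds) != 2L || bounds[1] >= bounds[2]) {
    abort("`bounds` must be an increasing length-2 interval.",
      class = "sanistunt_parameter_error"
    )
  }
  parts <- bc_design(data, outcome, exposure, covariates, weights)
  if (parts$n < 10L) {
    abort("Need at least 10 usable rows to estimate lambda.",
      class = "sanistunt_data_error"
    )
  }
  loglik_fn <- function(l) bc_loglik_at(parts, l)

  grid <- seq(bounds[1], bounds[2], by = grid_step)
  prof <- vapply(grid, loglik_fn, numeric(1))
  i_max <- which.max(prof)
  lo <- grid[max(1L, i_max - 1L)]
  hi <- grid[min(length(grid), i_max + 1L)]
  opt <- optimize(loglik_fn, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  lambda_hat <- opt$maximum
  max_ll <- opt$objective
  if (prof[i_max] > max_ll) { # grid point can beat the local refine
    lambda_hat <- grid[i_max]
    max_ll <- prof[i_max]
  }

  drop_ll <- qchisq(0.95, df = 1) / 2
  cutoff <- max_ll - drop_ll
  ci_root <- function(interval) {
    f <- function(l) loglik_fn(l) - cutoff
    if (f(interval[1]) > 0 && f(interval[2]) > 0) {
      return(NA_real_) # profile never drops below the cutoff inside bounds
    }
    uniroot(f, interval = sort(interval), tol = 1e-6)$root
  }
  ci_lower <- if (lambda_hat > bounds[1]) ci_root(c(bounds[1], lambda_hat)) else bounds[1]
  ci_upper <- if (lambda_hat < bounds[2]) ci_root(c(lambda_hat, bounds[2])) else bounds[2]
  if (is.na(ci_lower)) {
    warn("Profile does not drop 1.92 log-units below the maximum at the lower bound; CI truncated.")
    ci_lower <- bounds[1]
  }
  if (is.na(ci_upper)) {
    warn("Profile does not drop 1.92 log-units below the maximum at the upper bound; CI truncated.")
    ci_upper <- bounds[2]
  }

  fit <- structure(
    list(
      lambda_hat = lambda_hat,
      ci_95 = c(lower = ci_lower, upper = ci_upper),
      max_loglik = max_ll,
      profile = tibble(lambda = grid, loglik = prof),
      n = parts$n,
      outcome = outcome,
      exposure = exposure,
      bounds = bounds,
      loglik_fn = loglik_fn
    ),
    class = "boxcox_fit"
  )
  fit$lr_tests <- purrr::map_dfr(lr_null, function(l0) {
    stat <- 2 * (max_ll - loglik_fn(l0))
    tibble(
      lambda0 = l0, statistic = stat,
      p.value = pchisq(stat, df = 1, lower.tail = FALSE)
    )
  })
  fit
}

#' Likelihood-ratio test of a fixed transformation parameter
#'
#' Statistic `2 * (l(lambda_hat) - l(lambda0))` referred to chi-square with
#' 1 degree of freedom.
#'
#' @param fit A `boxcox_fit` from [estimate_boxcox_lambda()].
#' @param lambda0 Null value, inside the fit's search bounds.
#' @return A one-row tibble with `lambda0`, `statistic`, `p.value`.
#' @export
lr_test <- function(fit, lambda0) {
  if (!inherits(fit, "boxcox_fit")) {
    abort("`fit` must be a `boxcox_fit`.", class = "sanistunt_parameter_error")
  }
  check_number(lambda0, "lambda0")
  if (lambda0 < fit$bounds[1] || lambda0 > fit$bounds[2]) {
    abort("`lambda0` is outside the profiled range.",
      class = "sanistunt_parameter_error"
    )
  }
  stat <- max(0, 2 * (fit$max_loglik - fit$loglik_fn(lambda0)))
  tibble(
    lambda0 = lambda0, statistic = stat,
    p.value = pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat(sprintf(
    "Box-Cox transformation of `%s` (outcome `%s`, n = %d)\n",
    x$exposure, x$outcome, x$n
  ))
  cat(sprintf(
    "  lambda_hat = %.3f  (95%% CI %.2f to %.2f)\n",
    x$lambda_hat, x$ci_95[["lower"]], x$ci_95[["upper"]]
  ))
  for (i in seq_len(nrow(x$lr_tests))) {
    cat(sprintf(
      "  LR test lambda = %g: statistic %.2f, p = %.3g\n",
      x$lr_tests$lambda0[i], x$lr_tests$statistic[i], x$lr_tests$p.value[i]
    ))
  }
  invisible(x)
}

#' Tidy a Box-Cox fit
#'
#' @param x A `boxcox_fit`.
#' @param ... Unused.
#' @return One row per likelihood-ratio test, plus the estimate columns.
#' @method tidy boxcox_fit
#' @export
tidy.boxcox_fit <- function(x, ...) {
  dplyr::mutate(x$lr_tests,
    lambda_hat = x$lambda_hat,
    ci_lower = x$ci_95[["lower"]],
    ci_upper = x$ci_95[["upper"]],
    .before = 1
  )
}

#' @method glance boxcox_fit
#' @export
glance.boxcox_fit <- function(x, ...) {
  tibble(
    lambda_hat = x$lambda_hat,
    ci_lower = x$ci_95[["lower"]],
    ci_upper = x$ci_95[["upper"]],
    logLik = x$max_loglik,
    nobs = x$n
  )
}

#' Profile-likelihood plot for a Box-Cox fit
#'
#' @param object A `boxcox_fit`.
#' @param ... Unused.
#' @return A ggplot of the profile with the estimate, the 1.92-log-unit drop
#'   line, and the 95% CI.
#' @method autoplot boxcox_fit
#' @export
autoplot.boxcox_fit <- function(object, ...) {
  cutoff <- object$max_loglik - qchisq(0.95, 1) / 2
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$lambda, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$lambda_hat, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$ci_95, linetype = 3, colour = "grey40") +
    ggplot2::labs(
      x = expression(lambda), y = "Profile log-likelihood",
      title = sprintf(
        "Box-Cox profile: lambda_hat = %.3f (95%% CI %.2f, %.2f)",
        object$lambda_hat, object$ci_95[["lower"]], object$ci_95[["upper"]]
      )
    ) +
    ggplot2::theme_minimal()
}
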