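# Weighted least squares with heteroscedasticity-robust covariance: the
# estimator behind every regression in the package.

#' Describe one regression term
#'
#' A term is a source column plus a transform applied before the design matrix
#' is assembled: the column itself, its natural log, or its square.
#'
#' @param column Name of the source column.
#' @param transform One of `"identity"`, `"log"` (natural log, requires
#'   strictly positive values), `"square"`.
#' @return A `wls_term` object.
#' @seealso [wls_spec()]
#' @export
wls_term <- function(column, transform = c("identity", "log", "square")) {
  if (!is.character(column) || length(column) != 1L || is.na(column)) {
    abort("`column` must be a single column name.", class = "sanistunt_parameter_error")
  }
  transform <- match.arg(transform)
  structure(list(column = column, transform = transform), class = "wls_term")
}

term_label <- function(term) {
  switch(term$transform,
    identity = term$column,
    log = paste0("ln(", term$column, ")"),
    square = paste0(term$column, "^2")
  )
}

as_term_list <- function(terms) {
  if (inherits(terms, "wls_term")) terms <- list(terms)
  terms <- lapply(terms, function(t) {
    if (inherits(t, "wls_term")) t else wls_term(as.character(t))
  })
  terms
}

#' Specify a weighted regression model
#'
#' @param outcome Name of the outcome column.
#' @param terms List of [wls_term()] objects (bare column names are accepted
#'   and treated as identity terms). Order is preserved in output.
#' @param weights Name of a strictly positive weight column, or `NULL` for an
#'   unweighted fit.
#' @param intercept Include an intercept? Default `TRUE`.
#' @return A `wls_spec` object.
#' @examples
#' wls_spec("stunting_pct", list(wls_term("od_pct", "log")), weights = "population")
#' @export
wls_spec <- function(outcome, terms, weights = NULL, intercept = TRUE) {
  if (!is.character(outcome) || length(outcome) != 1L) {
    abort("`outcome` must be a single column name.", class = "sanistunt_parameter_error")
  }
  terms <- as_term_list(terms)
  if (length(terms) == 0L) {
    abort("`terms` must contain at least one term.", class = "sanistunt_parameter_error")
  }
  keys <- vapply(terms, function(t) paste(t$column, t$transform), character(1))
  if (anyDuplicated(keys)) {
    abort("Duplicate (column, transform) pairs in `terms`.",
      class = "sanistunt_parameter_error"
    )
  }
  structure(
    list(
      outcome = outcome, terms = terms, weights = weights,
      intercept = isTRUE(intercept)
    ),
    class = "wls_spec"
  )
}

#' @export
print.wls_spec <- function(x, ...) {
  rhs <- vapply(x$terms, term_label, character(1))
  cat(
    x$outcome, "~", paste(rhs, collapse = " + "),
    if (x$intercept) "+ 1" else "+ 0",
    if (!is.null(x$weights)) paste0(" [weights: ", x$weights, "]") else "",
    "\n"
  )
  invisible(x)
}

apply_transform <- function(x, term) {
  switch(term$transform,
    identity = x,
    log = {
      if (any(x <= 0)) {
        abort(
          sprintf(
            "Column `%s` must be strictly positive for a log term (min = %g).",
            term$column, min(x)
          ),
          class = "sanistunt_domain_error"
        )
      }
      log(x)
    },
    square = x^2
  )
}

build_design <- function(data, spec) {
  cols <- vapply(spec$terms, `[[`, character(1), "column")
  used <- unique(c(spec$outcome, cols, spec$weights))
  check_columns(data, used, "model data")
  keep <- complete.cases(data[used])
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    inform(sprintf(
      "Dropped %d row(s) with missing values in model columns (listwise deletion).",
      n_dropped
    ))
  }
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(data[[spec$outcome]])
  X <- vapply(
    spec$terms,
    function(t) apply_transform(as.numeric(data[[t$column]]), t),
    numeric(nrow(data))
  )
  X <- matrix(X, nrow = nrow(data))
  colnames(X) <- vapply(spec$terms, term_label, character(1))
  if (spec$intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  w <- if (is.null(spec$weights)) rep(1, nrow(data)) else as.numeric(data[[spec$weights]])
  if (any(w <= 0)) {
    abort("All weights must be strictly positive.", class = "sanistunt_data_error")
  }
  list(y = y, X = X, w = w, n_dropped = n_dropped)
}

#' Heteroscedasticity-robust (sandwich) covariance of WLS coefficients
#'
#' Sandwich estimator for (possibly weighted) least squares: bread
#' `(X'WX)^-1`, meat `sum_i (w_i e_i)^2 x_i x_i'` with the usual finite-sample
#' adjustments. `"HC1"` scales the meat by `n/(n-k)`; `"HC2"` and `"HC3"`
#' divide the squared residuals by `(1 - h_i)` and `(1 - h_i)^2`, where `h_i`
#' is the weighted leverage.
#'
#' @param design Numeric design matrix (n x k), including any intercept column.
#' @param residuals Length-n residual vector.
#' @param weights Length-n positive weights; `NULL` means equal weights.
#' @param type One of `"HC1"` (default), `"HC0"`, `"HC2"`, `"HC3"`.
#' @return A symmetric k x k covariance matrix with the design's column names.
#' @references White, H. (1980) Econometrica 48, 817-838; MacKinnon & White
#'   (1985) J. Econometrics 29, 305-325.
#' @export
hc_robust_cov <- function(design, residuals, weights = NULL,
                          type = c("HC1", "HC0", "HC2", "HC3")) {
  type <- match.arg(type)
  X <- as.matrix(design)
  n <- nrow(X)
  k <- ncol(X)
  e <- as.numeric(residuals)
  if (length(e) != n) {
    abort("`residuals` must have one value per design row.",
      class = "sanistunt_parameter_error"
    )
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w <= 0)) {
    abort("`weights` must be strictly positive, one per row.",
      class = "sanistunt_data_error"
    )
  }
  XtWX <- crossprod(X * w, X)
  bread <- tryCatch(
    solve(XtWX),
    error = function(err) {
      abort("Singular design: X'WX is not invertible.",
        class = "sanistunt_singular_design_error"
      )
    }
  )
  e2 <- (w * e)^2
  e2 <- switch(type,
    HC0 = e2,
    HC1 = e2 * n / (n - k),
    HC2 = ,
    HC3 = {
      # weighted leverages h_i = w_i x_i' (X'WX)^-1 x_i
      h <- rowSums((X %*% bread) * X) * w
      h <- pmin(h, 1 - .Machine$double.eps^0.5)
      if (type == "HC2") e2 / (1 - h) else e2 / (1 - h)^2
    }
  )
  meat <- crossprod(X, X * e2) # X' diag(e2) X
  V <- bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Two-sided p-value from the t distribution
#'
#' @param t t statistic (vectorized).
#' @param dof Degrees of freedom, at least 1.
#' @return `2 * P(T >= |t|)` for `T ~ t(dof)`.
#' @export
two_sided_p <- function(t, dof) {
  check_number(dof, "dof", min = 1)
  2 * pt(abs(t), df = dof, lower.tail = FALSE)
}

#' Fit a weighted least-squares regression with robust standard errors
#'
#' Districts (rows) are weighted as analytic weights: weights are rescaled to
#' sum to the number of used observations, so estimates and standard errors
#' are invariant to the overall scale of the weight column. Rows with missing
#' values in any used column are dropped (listwise deletion) with a message.
#' Inference is t-based with `n - k` degrees of freedom.
#'
#' @param data A data frame of observations.
#' @param spec A [wls_spec()].
#' @param se_type Covariance estimator for standard errors: `"HC1"` (default,
#'   heteroscedasticity-robust with `n/(n-k)` scaling), `"HC0"`, `"HC2"`,
#'   `"HC3"`, or `"classical"` (homoscedastic).
#' @return A `wls_fit` object; see [tidy.wls_fit()] and [glance.wls_fit()].
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(1, 3, 2, 5, 4))
#' fit <- fit_wls(d, wls_spec("y", list(wls_term("x"))))
#' coef(fit) # intercept 0.6, slope 0.8
#' @export
fit_wls <- function(data, spec, se_type = c("HC1", "HC0", "HC2", "HC3", "classical")) {
  se_type <- match.arg(se_type)
  if (!inherits(spec, "wls_spec")) {
    abort("`spec` must be a `wls_spec` object.", class = "sanistunt_parameter_error")
  }
  parts <- build_design(data, spec)
  y <- parts$y
  X <- parts$X
  n <- length(y)
  k <- ncol(X)
  if (n <= k) {
    abort(sprintf("Need more observations (%d) than parameters (%d).", n, k),
      class = "sanistunt_data_error"
    )
  }
  # analytic-weight convention: rescale to sum to n
  w <- parts$w * n / sum(parts$w)

  qrx <- qr(X * sqrt(w))
  if (qrx$rank < k) {
    bad <- colnames(X)[qrx$pivot[seq(qrx$rank + 1L, k)]]
    abort(
      sprintf(
        "Singular design: term(s) %s are collinear with earlier terms.",
        paste0("`", bad, "`", collapse = ", ")
      ),
      class = "sanistunt_singular_design_error"
    )
  }
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  e <- y - drop(X %*% beta)
  wmean_y <- sum(w * y) / sum(w)
  tss <- sum(w * (y - wmean_y)^2)
  rss <- sum(w * e^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  dof <- n - k
  V <- if (se_type == "classical") {
    sigma2 <- rss / dof
    Vc <- sigma2 * solve(crossprod(X * sqrt(w)))
    dimnames(Vc) <- list(colnames(X), colnames(X))
    (Vc + t(Vc)) / 2
  } else {
    hc_robust_cov(X, e, w, type = se_type)
  }
  se <- sqrt(diag(V))
  tstat <- beta / se
  structure(
    list(
      coefficients = beta,
      std_error = se,
      t_stats = tstat,
      p_values = two_sided_p(tstat, dof),
      r_squared = r2,
      n_obs = n,
      n_params = k,
      df_residual = dof,
      residuals = e,
      fitted = drop(X %*% beta),
      weights = w,
      vcov = V,
      se_type = se_type,
      n_dropped = parts$n_dropped,
      spec = spec
    ),
    class = "wls_fit"
  )
}

#' @export
coef.wls_fit <- function(object, ...) object$coefficients

#' @export
vcov.wls_fit <- function(object, ...) object$vcov

#' @export
residuals.wls_fit <- function(object, ...) object$residuals

#' @export
nobs.wls_fit <- function(object, ...) object$n_obs

#' @export
print.wls_fit <- function(x, digits = 4, ...) {
  cat("Weighted least squares (", x$se_type, " standard errors)\n", sep = "")
  print(x$spec)
  out <- data.frame(
    estimate = signif(x$coefficients, digits),
    std.error = signif(x$std_error, digits),
    statistic = signif(x$t_stats, digits),
    p.value = signif(x$p_values, digits)
  )
  print(out)
  cat(sprintf(
    "n = %d, k = %d, weighted R-squared = %.4f\n",
    x$n_obs, x$n_params, x$r_squared
  ))
  invisible(x)
}

#' Tidy a WLS fit
#'
#' @param x A `wls_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy wls_fit
#' @export
tidy.wls_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_error),
    statistic = unname(x$t_stats),
    p.value = unname(x$p_values)
  )
}

#' One-row model summary of a WLS fit
#'
#' @param x A `wls_fit`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `df.residual`, `nobs`, `n.dropped`,
#'   `se.type`.
#' @method glance wls_fit
#' @export
glance.wls_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    df.residual = x$df_residual,
    nobs = x$n_obs,
    n.dropped = x$n_dropped,
    se.type = x$se_type
  )
}

#' Observed-versus-fitted plot for a WLS fit
#'
#' Point area is proportional to the analytic weight, echoing the convention
#' of population-weighted district scatter plots.
#'
#' @param object A `wls_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wls_fit
#' @export
autoplot.wls_fit <- function(object, ...) {
  df <- tibble(
    fitted = object$fitted,
    observed = object$fitted + object$residuals,
    weight = object$weights
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(
      x = "Fitted value", y = "Observed value",
      title = paste0(
        object$spec$outcome, ": observed vs fitted (R² = ",
        sprintf("%.3f", object$r_squared), ")"
      )
    ) +
    ggplot2::theme_minimal()
}
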