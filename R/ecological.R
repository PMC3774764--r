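# The district-level pipeline: descriptive statistics, the five-stage
# population-weighted model sequence for stunting and severe stunting,
# bivariate fits, the marginal-effect and gap-share summaries, and a
# text/CSV rendering of the staged table.

#' Descriptive statistics of a district table
#'
#' Unweighted mean, min, max, and moment-ratio skewness per variable, after
#' dropping missing values column-wise. A constant column has undefined
#' skewness and reports `NA`.
#'
#' @param data A data frame.
#' @param variables Columns to summarize; default all numeric columns.
#' @return A tibble with `variable`, `n`, `mean`, `min`, `max`, `skewness`.
#' @examples
#' d <- simulate_districts(district_sim_params(seed = 1))
#' descriptive_stats(d)
#' @export
descriptive_stats <- function(data, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  check_columns(data, variables, "data")
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    x <- x[!is.na(x)]
    if (length(x) < 2L) {
      abort(sprintf("Need at least 2 non-missing values in `%s`.", v),
        class = "sanistunt_data_error"
      )
    }
    tibble(
      variable = v, n = length(x), mean = mean(x), min = min(x),
      max = max(x), skewness = sample_skewness(x)
    )
  })
}

stage_terms <- function() {
  list(
    list(wls_term("od_pct", "log")),
    list(wls_term("urban_pct"), wls_term("urban_pct", "square")),
    list(
      wls_term("mpce", "log"), wls_term("calories"),
      wls_term("cereal_calories"), wls_term("household_size")
    ),
    list(wls_term("literacy_pct"), wls_term("literacy_female_pct")),
    list(wls_term("imr"))
  )
}

#' Model specification for one adjustment stage
#'
#' The staged sequence adds controls cumulatively: (1) `ln(od_pct)` only;
#' (2) urban share as a quadratic in the raw percent; (3) economic controls
#' `ln(mpce)`, calories, cereal calories, household size; (4) overall and
#' female literacy; (5) the infant mortality rate, as a probe of the
#' early-life disease environment rather than a further confounder. All
#' stages weight districts by `population`.
#'
#' @param stage Integer 1-5.
#' @param outcome Outcome column, `"stunting_pct"` or `"severe_stunting_pct"`.
#' @param weights Weight column (default `"population"`).
#' @return A [wls_spec()].
#' @export
build_stage_spec <- function(stage, outcome = "stunting_pct", weights = "population") {
  stage <- check_count(stage, "stage", min = 1L)
  if (stage > 5L) {
    abort("`stage` must be between 1 and 5.", class = "sanistunt_parameter_error")
  }
  terms <- purrr::flatten(stage_terms()[seq_len(stage)])
  wls_spec(outcome, terms, weights = weights)
}

#' Fit the five-stage adjustment sequence
#'
#' Fits each stage via [fit_wls()] with population weights and
#' heteroscedasticity-robust (HC1) standard errors; rows with missing values
#' are dropped per stage (listwise deletion), so stage 5 typically uses fewer
#' districts when IMR is incomplete.
#'
#' @param data District table satisfying the district schema.
#' @param outcome `"stunting_pct"` or `"severe_stunting_pct"`.
#' @param stages Which stages to fit (default `1:5`).
#' @param se_type Passed to [fit_wls()] (default `"HC1"`).
#' @return A `staged_fits` object; `tidy()` gives the long coefficient table
#'   with significance stars, `glance()` the per-stage R-squared and n.
#' @examples
#' d <- simulate_districts(district_sim_params(seed = 1))
#' fits <- run_staged_models(d, "stunting_pct")
#' glance(fits)
#' @export
run_staged_models <- function(data, outcome = c("stunting_pct", "severe_stunting_pct"),
                              stages = 1:5, se_type = "HC1") {
  outcome <- match.arg(outcome)
  fits <- lapply(stages, function(s) {
    fit_wls(data, build_stage_spec(s, outcome), se_type = se_type)
  })
  names(fits) <- paste0("stage_", stages)
  structure(
    list(
      fits = fits, stages = stages, outcome = outcome,
      star_thresholds = c(`**` = 0.01, `*` = 0.05, `†` = 0.10)
    ),
    class = "staged_fits"
  )
}

#' Significance stars by strict two-sided p-value thresholds
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.05, a dagger for p < 0.10, else
#' empty; thresholds are strict, so p = 0.10 exactly earns no mark.
#'
#' @param p Vector of p-values.
#' @return Character vector of marks.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.10 ~ "†",
    TRUE ~ ""
  )
}

#' Tidy a staged model sequence
#'
#' @param x A `staged_fits` object.
#' @param ... Unused.
#' @return A tibble with `stage`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `stars`.
#' @method tidy staged_fits
#' @export
tidy.staged_fits <- function(x, ...) {
  purrr::map2_dfr(x$fits, x$stages, function(fit, s) {
    dplyr::mutate(tidy(fit), stage = s, stars = significance_stars(.data$p.value), .before = 1)
  })
}

#' Per-stage fit summary
#'
#' @param x A `staged_fits` object.
#' @param ... Unused.
#' @return A tibble with `stage`, `r.squared`, `nobs`, `n.dropped`.
#' @method glance staged_fits
#' @export
glance.staged_fits <- function(x, ...) {
  purrr::map2_dfr(x$fits, x$stages, function(fit, s) {
    dplyr::mutate(glance(fit), stage = s, .before = 1)
  })
}

#' @export
print.staged_fits <- function(x, ...) {
  cat("Staged population-weighted models for", x$outcome, "\n\n")
  print(format_stage_table(x), n = Inf)
  invisible(x)
}

#' Render a staged model table
#'
#' One column per stage; each coefficient occupies two rows — the estimate
#' (4 significant figures) with its significance mark, and the robust
#' standard error in parentheses beneath — followed by `n` and `R2` rows, as
#' in conventional journal regression tables.
#'
#' @param x A `staged_fits` object.
#' @param digits Significant figures for display (default 4).
#' @return A character tibble with columns `term`, `row` and one column per
#'   stage label `"(1)"` ... `"(5)"`.
#' @export
format_stage_table <- function(x, digits = 4) {
  long <- tidy(x)
  terms <- unique(long$term)
  terms <- c(setdiff(terms, "(Intercept)"), "(Intercept)")
  stage_lab <- function(s) sprintf("(%d)", s)
  out <- purrr::map_dfr(terms, function(tm) {
    coef_row <- list(term = tm, row = "estimate")
    se_row <- list(term = tm, row = "se")
    for (s in x$stages) {
      rec <- dplyr::filter(long, .data$stage == s, .data$term == tm)
      lab <- stage_lab(s)
      if (nrow(rec) == 0) {
        coef_row[[lab]] <- ""
        se_row[[lab]] <- ""
      } else {
        coef_row[[lab]] <- paste0(signif(rec$estimate, digits), rec$stars)
        se_row[[lab]] <- paste0("(", signif(rec$std.error, digits), ")")
      }
    }
    dplyr::bind_rows(as_tibble(coef_row), as_tibble(se_row))
  })
  gl <- glance(x)
  footer <- purrr::map_dfr(c("n", "R2"), function(what) {
    row <- list(term = what, row = "stat")
    for (s in x$stages) {
      g <- dplyr::filter(gl, .data$stage == s)
      row[[stage_lab(s)]] <- if (what == "n") {
        as.character(g$nobs)
      } else {
        as.character(signif(g$r.squared, 3))
      }
    }
    as_tibble(row)
  })
  dplyr::bind_rows(out, footer)
}

#' Coefficient paths across adjustment stages
#'
#' @param object A `staged_fits` object.
#' @param terms Terms to display (default the exposure, `ln(od_pct)`).
#' @param ... Unused.
#' @return A ggplot of estimates with ±1.96 robust-SE intervals by stage.
#' @method autoplot staged_fits
#' @export
autoplot.staged_fits <- function(object, terms = "ln(od_pct)", ...) {
  long <- dplyr::filter(tidy(object), .data$term %in% terms)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$stage), y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$std.error,
      ymax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
    ggplot2::labs(
      x = "Adjustment stage", y = "Coefficient (pp per unit)",
      title = paste("Coefficient stability across stages:", object$outcome)
    ) +
    ggplot2::theme_minimal()
}

#' Population-weighted bivariate district regression
#'
#' A stage-1-style weighted fit of an outcome on a single untransformed
#' predictor, the form behind simple exposure-outcome district scatter plots;
#' reported with its weighted R-squared.
#'
#' @param data District table.
#' @param outcome Outcome column.
#' @param predictor Predictor column (entered untransformed).
#' @param weights Weight column (default `"population"`).
#' @return A `wls_fit`.
#' @export
bivariate_district_fit <- function(data, outcome, predictor, weights = "population") {
  fit_wls(data, wls_spec(outcome, list(wls_term(predictor)), weights = weights))
}

#' Marginal effect of a proportional increase in open defecation
#'
#' With stunting linear in `ln(OD)`, a `pct_increase`% proportional rise in
#' open defecation changes predicted prevalence by
#' `coef_ln_od * ln(1 + pct_increase/100)` percentage points. The additive
#' log-point approximation `coef_ln_od * pct_increase/100` is available via
#' `method = "log_points"`; for a 10% rise the two agree to the first
#' decimal.
#'
#' @param coef_ln_od Coefficient on `ln(OD)`, in pp per log-unit.
#' @param pct_increase Proportional increase in percent (> -100; default 10).
#' @param method `"proportional"` (default) or `"log_points"`.
#' @return Change in prevalence, percentage points.
#' @examples
#' marginal_effect(7.082, 10) # ~0.675 pp, i.e. ~0.7 after rounding
#' @export
marginal_effect <- function(coef_ln_od, pct_increase = 10,
                            method = c("proportional", "log_points")) {
  method <- match.arg(method)
  check_number(coef_ln_od, "coef_ln_od")
  check_number(pct_increase, "pct_increase", min = -100, strict_min = TRUE)
  switch(method,
    proportional = coef_ln_od * log1p(pct_increase / 100),
    log_points = coef_ln_od * pct_increase / 100
  )
}

#' Share of a stunting gap statistically attributable to open defecation
#'
#' For two groups of districts (a low-performing group with high stunting and
#' a high-performing group with low stunting), the log-linear model ascribes
#' `coef_ln_od * (ln(od_low) - ln(od_high))` percentage points of the
#' stunting difference to the open-defecation difference; dividing by the
#' observed gap `stunting_low - stunting_high` gives the attributable share.
#' Antisymmetric under swapping the two groups.
#'
#' @param coef_ln_od Coefficient on `ln(OD)`, pp per log-unit.
#' @param od_low_pct,od_high_pct Open-defecation percent in the low- and
#'   high-performing groups, each in (0, 100].
#' @param stunting_low_pct,stunting_high_pct Stunting percent in the two
#'   groups; must differ.
#' @return The attributable fraction (can exceed 1 or be negative if the
#'   model over- or mis-ascribes the gap).
#' @examples
#' gap_share(11.02, od_low_pct = 76.3, od_high_pct = 33.8,
#'           stunting_low_pct = 59.1, stunting_high_pct = 35.9) # ~0.39
#' @export
gap_share <- function(coef_ln_od, od_low_pct, od_high_pct,
                      stunting_low_pct, stunting_high_pct) {
  check_number(coef_ln_od, "coef_ln_od")
  check_number(od_low_pct, "od_low_pct", min = 0, max = 100, strict_min = TRUE)
  check_number(od_high_pct, "od_high_pct", min = 0, max = 100, strict_min = TRUE)
  check_number(stunting_low_pct, "stunting_low_pct", min = 0, max = 100)
  check_number(stunting_high_pct, "stunting_high_pct", min = 0, max = 100)
  gap <- stunting_low_pct - stunting_high_pct
  if (gap == 0) {
    abort("The stunting gap is zero; the share is undefined.",
      class = "sanistunt_domain_error"
    )
  }
  coef_ln_od * (log(od_low_pct) - log(od_high_pct)) / gap
}
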