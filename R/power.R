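# Monte Carlo study of the power cost of dichotomizing child height: repeated
# subsamples are collapsed to PSU means and the continuous outcome (mean HAZ)
# is raced against the dichotomized ones (fraction stunted / severely
# stunted) in bivariate regressions on the PSU open-defecation fraction.

#' Classify height-for-age z-scores into stunting indicators
#'
#' Stunted means HAZ strictly below -2; severely stunted strictly below -3.
#' Severe implies stunted.
#'
#' @param haz Finite height-for-age z-scores.
#' @return A tibble with logical columns `stunted`, `severe`.
#' @examples
#' classify_child(c(-2.5, -2, -4))
#' @export
classify_child <- function(haz) {
  if (!is.numeric(haz) || any(!is.finite(haz))) {
    abort("`haz` must be finite numeric z-scores.", class = "sanistunt_data_error")
  }
  tibble(stunted = haz < -2, severe = haz < -3)
}

#' Collapse child records to PSU means
#'
#' One row per distinct PSU: the fraction of sampled households practicing
#' open defecation, mean HAZ, the fractions stunted (HAZ < -2) and severely
#' stunted (HAZ < -3), and the number of sampled children, all over that
#' PSU's sampled children only.
#'
#' @param children Tibble with `psu_id`, `od_household` (0/1), `haz`.
#' @return A tibble with `psu_id`, `od_fraction`, `mean_haz`, `frac_stunted`,
#'   `frac_severe`, `n_children`, ordered by `psu_id`.
#' @export
collapse_to_psu <- function(children) {
  check_columns(children, child_cols, "child data")
  if (nrow(children) == 0L) {
    abort("`children` must be non-empty.", class = "sanistunt_data_error")
  }
  if (!all(children$od_household %in% c(0, 1))) {
    abort("`od_household` must be 0/1.", class = "sanistunt_data_error")
  }
  if (any(!is.finite(children$haz))) {
    abort("`haz` must be finite.", class = "sanistunt_data_error")
  }
  flags <- classify_child(children$haz)
  g <- factor(children$psu_id)
  sums <- rowsum(
    cbind(
      od = as.numeric(children$od_household), haz = children$haz,
      st = as.numeric(flags$stunted), sv = as.numeric(flags$severe), n = 1
    ),
    g, reorder = TRUE
  )
  n <- unname(sums[, "n"])
  tibble(
    psu_id = rownames(sums),
    od_fraction = unname(sums[, "od"]) / n,
    mean_haz = unname(sums[, "haz"]) / n,
    frac_stunted = unname(sums[, "st"]) / n,
    frac_severe = unname(sums[, "sv"]) / n,
    n_children = as.integer(n)
  )
}

#' Bivariate PSU-level regression
#'
#' Unweighted OLS of one collapsed outcome on the PSU open-defecation
#' fraction, with classical standard errors: the per-replicate regression of
#' the power study.
#'
#' @param summaries PSU summary tibble from [collapse_to_psu()].
#' @param outcome `"mean_haz"`, `"frac_stunted"`, or `"frac_severe"`.
#' @return One-row tibble with `outcome`, `slope`, `t_stat`, `r_squared`,
#'   `n_psu`.
#' @export
bivariate_psu_regression <- function(summaries,
                                     outcome = c("mean_haz", "frac_stunted", "frac_severe")) {
  outcome <- match.arg(outcome)
  check_columns(summaries, c("od_fraction", outcome), "PSU summaries")
  if (nrow(summaries) < 3L) {
    abort("Need at least 3 PSU summaries to regress.", class = "sanistunt_data_error")
  }
  fit <- fit_wls(
    summaries,
    wls_spec(outcome, list(wls_term("od_fraction"))),
    se_type = "classical"
  )
  tibble(
    outcome = outcome,
    slope = unname(coef(fit)["od_fraction"]),
    t_stat = unname(fit$t_stats["od_fraction"]),
    r_squared = fit$r_squared,
    n_psu = fit$n_obs
  )
}

power_outcomes <- c("mean_haz", "frac_stunted", "frac_severe")

win_fractions <- function(replicates) {
  wide_r2 <- tidyr::pivot_wider(
    replicates[c("rep", "outcome", "r_squared")],
    names_from = "outcome", values_from = "r_squared"
  )
  wide_t <- tidyr::pivot_wider(
    replicates[c("rep", "outcome", "t_stat")],
    names_from = "outcome", values_from = "t_stat"
  )
  tibble(
    metric = c("r_squared", "abs_t"),
    win_fraction = c(
      mean(wide_r2$mean_haz > wide_r2$frac_stunted &
        wide_r2$mean_haz > wide_r2$frac_severe),
      mean(abs(wide_t$mean_haz) > abs(wide_t$frac_stunted) &
        abs(wide_t$mean_haz) > abs(wide_t$frac_severe))
    )
  )
}

#' Monte Carlo study of dichotomization and statistical power
#'
#' Repeats `n_reps` times: draw a simple random sample of `sample_size`
#' children without replacement, collapse to PSU means
#' ([collapse_to_psu()]; every PSU with at least `min_psu_n` sampled children
#' enters), and run the three bivariate PSU regressions
#' ([bivariate_psu_regression()]). The summary reports win fractions: the
#' share of replicates in which the continuous mean-HAZ regression's
#' R-squared strictly exceeds both dichotomized regressions' R-squared, and
#' likewise for |t| (absolute value, since the continuous and dichotomized
#' slopes have opposite signs).
#'
#' @param children Child tibble (`psu_id`, `od_household`, `haz`).
#' @param sample_size Children drawn per replicate (default 20,000).
#' @param n_reps Number of replicates (default 1,000).
#' @param seed Optional RNG seed for reproducibility.
#' @param min_psu_n Minimum sampled children for a PSU to enter the
#'   regressions (default 1).
#' @return A `power_study` object: `replicates` (tibble of `rep`, `outcome`,
#'   `slope`, `t_stat`, `r_squared`, `n_psu`), `summary` (win fractions),
#'   `n_reps`, `sample_size`, `seed`.
#' @examples
#' kids <- simulate_children(child_sim_params(n_psu = 50, children_per_psu = 10, seed = 1))
#' ps <- run_power_study(kids, sample_size = 250, n_reps = 20, seed = 2)
#' ps$summary
#' @export
run_power_study <- function(children, sample_size = 20000, n_reps = 1000,
                            seed = NULL, min_psu_n = 1) {
  check_columns(children, child_cols, "child data")
  sample_size <- check_count(sample_size, "sample_size", min = 3L)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  min_psu_n <- check_count(min_psu_n, "min_psu_n", min = 1L)
  n_pop <- nrow(children)
  if (sample_size > n_pop) {
    abort(sprintf(
      "`sample_size` (%d) exceeds the child population (%d).",
      sample_size, n_pop
    ), class = "sanistunt_parameter_error")
  }
  replicates <- with_optional_seed(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      idx <- sample.int(n_pop, sample_size, replace = FALSE)
      psu <- collapse_to_psu(children[idx, , drop = FALSE])
      if (min_psu_n > 1L) {
        psu <- dplyr::filter(psu, .data$n_children >= min_psu_n)
      }
      dplyr::mutate(
        purrr::map_dfr(power_outcomes, function(o) bivariate_psu_regression(psu, o)),
        rep = r, .before = 1
      )
    })
  })
  structure(
    list(
      replicates = replicates,
      summary = win_fractions(replicates),
      n_reps = n_reps,
      sample_size = sample_size,
      seed = seed
    ),
    class = "power_study"
  )
}

#' @export
print.power_study <- function(x, ...) {
  cat(sprintf(
    "Dichotomization power study: %d replicates of %d children\n",
    x$n_reps, x$sample_size
  ))
  print(x$summary)
  invisible(x)
}

#' Tidy the replicate table of a power study
#'
#' @param x A `power_study`.
#' @param ... Unused.
#' @return The replicate-level tibble (`rep`, `outcome`, `slope`, `t_stat`,
#'   `r_squared`, `n_psu`).
#' @method tidy power_study
#' @export
tidy.power_study <- function(x, ...) x$replicates

#' One-row summary of a power study
#'
#' @param x A `power_study`.
#' @param ... Unused.
#' @return A tibble with the two win fractions, `n_reps`, `sample_size`.
#' @method glance power_study
#' @export
glance.power_study <- function(x, ...) {
  tibble(
    r2_win_fraction = x$summary$win_fraction[x$summary$metric == "r_squared"],
    abs_t_win_fraction = x$summary$win_fraction[x$summary$metric == "abs_t"],
    n_reps = x$n_reps,
    sample_size = x$sample_size
  )
}

#' Histogram-ready distributions of R-squared and t statistics
#'
#' Bins each metric on a common break set across the three outcomes, so the
#' three distributions are directly comparable; per outcome the bin counts
#' sum to the number of replicates.
#'
#' @param result A `power_study`.
#' @param bins Number of bins per metric (default 30).
#' @return A list with `histograms` (tibble: `metric`, `outcome`, `bin_lo`,
#'   `bin_hi`, `bin_mid`, `count`) and `win_fractions`.
#' @export
summarize_distributions <- function(result, bins = 30) {
  if (!inherits(result, "power_study")) {
    abort("`result` must be a `power_study`.", class = "sanistunt_parameter_error")
  }
  bins <- check_count(bins, "bins", min = 1L)
  reps <- result$replicates
  one_metric <- function(metric, values_col) {
    v_all <- reps[[values_col]]
    rng <- range(v_all)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) # degenerate: point mass
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    purrr::map_dfr(power_outcomes, function(o) {
      v <- reps[[values_col]][reps$outcome == o]
      idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
      counts <- tabulate(idx, nbins = bins)
      tibble(
        metric = metric, outcome = o,
        bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
        bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
        count = counts
      )
    })
  }
  list(
    histograms = dplyr::bind_rows(
      one_metric("r_squared", "r_squared"),
      one_metric("t_stat", "t_stat")
    ),
    win_fractions = result$summary
  )
}

#' Distribution plots for a power study
#'
#' Overlaid histograms of per-replicate R-squared and t statistics for the
#' continuous and dichotomized outcomes; the continuous distribution sitting
#' to the right signals greater statistical power.
#'
#' @param object A `power_study`.
#' @param metric `"r_squared"` or `"t_stat"`.
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_study
#' @export
autoplot.power_study <- function(object, metric = c("r_squared", "t_stat"),
                                 bins = 30, ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(
    object$replicates,
    ggplot2::aes(x = .data[[metric]], fill = .data$outcome)
  ) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::labs(
      x = if (metric == "r_squared") expression(R^2) else "t statistic",
      y = "Replicates",
      title = "Dichotomization reduces statistical power"
    ) +
    ggplot2::theme_minimal()
}
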