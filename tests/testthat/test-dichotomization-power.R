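# PSU collapse, bivariate PSU regressions, and the Monte Carlo power study.

test_that("stunting thresholds are strict and nested", {
  cc <- classify_child(c(-2.5, -2, -4, -3, 0))
  expect_equal(cc$stunted, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(cc$severe, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_true(all(!cc$severe | cc$stunted)) # severe implies stunted
  expect_error(classify_child(c(-1, NA)), class = "sanistunt_data_error")
  expect_error(classify_child(Inf), class = "sanistunt_data_error")
})

test_that("PSU collapse reproduces hand-computed means and fractions", {
  one <- tibble::tibble(
    psu_id = "X", od_household = c(1, 1, 0, 0), haz = c(-3, -1, -1, -1)
  )
  s <- collapse_to_psu(one)
  expect_equal(s$od_fraction, 0.5)
  expect_equal(s$mean_haz, -1.5)
  expect_equal(s$frac_stunted, 0.25)
  expect_equal(s$frac_severe, 0)

  s3 <- collapse_to_psu(psu_fixture())
  expect_equal(s3$psu_id, c("A", "B", "C"))
  # spreadsheet-style hand values for the 3-PSU fixture
  expect_equal(s3$od_fraction, c(2 / 3, 0, 3 / 4))
  expect_equal(s3$mean_haz, c(-13 / 6, -1, -2))
  expect_equal(s3$frac_stunted, c(2 / 3, 0, 2 / 4))
  expect_equal(s3$frac_severe, c(0, 0, 1 / 4)) # haz = -3 exactly is not severe
  expect_equal(s3$n_children, c(3L, 2L, 4L))
  expect_true(all(s3$frac_severe <= s3$frac_stunted))
})

test_that("the bivariate PSU regression matches a normal-equations oracle and is order-invariant", {
  s <- tibble::tibble(
    psu_id = letters[1:5],
    od_fraction = c(0.1, 0.3, 0.5, 0.7, 0.9),
    mean_haz = c(-1.1, -1.6, -1.9, -2.6, -2.8),
    frac_stunted = c(0.2, 0.3, 0.5, 0.6, 0.8),
    frac_severe = c(0.1, 0.1, 0.2, 0.4, 0.5),
    n_children = rep(10L, 5)
  )
  r <- bivariate_psu_regression(s, "mean_haz")
  X <- cbind(1, s$od_fraction)
  beta <- ols_oracle(X, s$mean_haz)
  expect_equal(r$slope, beta[2], tolerance = 1e-10)
  e <- s$mean_haz - drop(X %*% beta)
  sigma2 <- sum(e^2) / 3
  se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
  expect_equal(r$t_stat, beta[2] / se, tolerance = 1e-10)
  r2 <- 1 - sum(e^2) / sum((s$mean_haz - mean(s$mean_haz))^2)
  expect_equal(r$r_squared, r2, tolerance = 1e-10)

  shuffled <- s[c(4, 1, 5, 3, 2), ]
  expect_equal(bivariate_psu_regression(shuffled, "mean_haz"), r)

  # exact fit when the outcome is perfectly linear in od_fraction
  s$mean_haz <- -1 - 2 * s$od_fraction
  expect_equal(bivariate_psu_regression(s, "mean_haz")$r_squared, 1, tolerance = 1e-12)

  expect_error(bivariate_psu_regression(s[1:2, ], "mean_haz"),
    class = "sanistunt_data_error"
  )
})

test_that("the power study is seed-reproducible and internally consistent", {
  kids <- simulate_children(child_sim_params(n_psu = 80, children_per_psu = 10, seed = 41))
  ps1 <- run_power_study(kids, sample_size = 400, n_reps = 5, seed = 42)
  ps2 <- run_power_study(kids, sample_size = 400, n_reps = 5, seed = 42)
  expect_identical(ps1$replicates, ps2$replicates)
  expect_identical(ps1$summary, ps2$summary)

  # pipeline consistency: replicate 1 equals a by-hand rerun of the same draw
  idx <- withr::with_seed(42L, sample.int(nrow(kids), 400, replace = FALSE))
  psu <- collapse_to_psu(kids[idx, ])
  manual <- purrr::map_dfr(
    c("mean_haz", "frac_stunted", "frac_severe"),
    function(o) bivariate_psu_regression(psu, o)
  )
  rep1 <- dplyr::select(
    dplyr::filter(ps1$replicates, rep == 1), -rep
  )
  expect_equal(as.data.frame(rep1), as.data.frame(manual), tolerance = 1e-12)

  # win fractions recount from the raw replicate table
  wide <- tidyr::pivot_wider(ps1$replicates[c("rep", "outcome", "r_squared")],
    names_from = "outcome", values_from = "r_squared"
  )
  recount <- mean(wide$mean_haz > wide$frac_stunted & wide$mean_haz > wide$frac_severe)
  expect_equal(ps1$summary$win_fraction[ps1$summary$metric == "r_squared"], recount)

  expect_error(run_power_study(kids, sample_size = nrow(kids) + 1, n_reps = 1),
    class = "sanistunt_parameter_error"
  )
})

test_that("distribution summaries conserve replicate counts and degenerate to a point mass", {
  kids <- simulate_children(child_sim_params(n_psu = 60, children_per_psu = 8, seed = 43))
  ps <- run_power_study(kids, sample_size = 240, n_reps = 12, seed = 44)
  sd12 <- summarize_distributions(ps, bins = 10)
  counts <- dplyr::summarise(
    dplyr::group_by(sd12$histograms, metric, outcome),
    total = sum(count), .groups = "drop"
  )
  expect_true(all(counts$total == 12L))
  expect_equal(sd12$win_fractions, ps$summary)

  ps1 <- run_power_study(kids, sample_size = 240, n_reps = 1, seed = 45)
  sd1 <- summarize_distributions(ps1, bins = 7)
  per <- dplyr::summarise(
    dplyr::group_by(sd1$histograms, metric, outcome),
    nonzero = sum(count > 0), .groups = "drop"
  )
  expect_true(all(per$nonzero == 1L)) # single point mass per outcome
})

test_that("a step-function outcome makes dichotomized and continuous R2 coincide", {
  # PSU OD fractions are deterministic (all-0 or all-1 households); child haz
  # is an exact step of the PSU rate across the -2 cutoff, so mean HAZ and
  # the stunting fraction carry identical information
  n_psu <- 20
  rate <- rep(c(0, 1), length.out = n_psu)
  kids <- tibble::tibble(
    psu_id = rep(sprintf("P%02d", 1:n_psu), each = 5),
    od_household = rep(rate, each = 5),
    haz = ifelse(rep(rate, each = 5) == 1, -2.5, -1.5)
  )
  psu <- collapse_to_psu(kids)
  r_cont <- bivariate_psu_regression(psu, "mean_haz")$r_squared
  r_dich <- bivariate_psu_regression(psu, "frac_stunted")$r_squared
  expect_equal(r_cont, 1, tolerance = 1e-12)
  expect_equal(r_dich, r_cont, tolerance = 1e-12)
})

test_that("the continuous outcome's win fraction rises with the scaled effect size", {
  # weak-to-moderate effects: power is the binding constraint here. (At very
  # large effects the PSU means center on the -2 cutoff, where a binary
  # indicator is maximally informative and the race tightens again.)
  wf <- vapply(c(-0.15, -0.6, -1.5), function(delta) {
    kids <- simulate_children(child_sim_params(
      n_psu = 150, children_per_psu = 10, delta_haz = delta, haz_sd = 1.2,
      seed = 46
    ))
    ps <- run_power_study(kids, sample_size = 750, n_reps = 40, seed = 47)
    glance(ps)$r2_win_fraction
  }, numeric(1))
  expect_true(all(diff(wf) >= 0))
  expect_gt(wf[3], wf[1])
})

test_that("min_psu_n filters small PSUs out of the replicate regressions", {
  kids <- simulate_children(child_sim_params(n_psu = 50, children_per_psu = 10, seed = 48))
  ps_all <- run_power_study(kids, sample_size = 100, n_reps = 2, seed = 49)
  ps_flt <- run_power_study(kids, sample_size = 100, n_reps = 2, seed = 49, min_psu_n = 3)
  expect_true(all(ps_flt$replicates$n_psu <= ps_all$replicates$n_psu))
})
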