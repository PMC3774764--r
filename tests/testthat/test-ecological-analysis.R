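# Descriptives, the staged model sequence, marginal effects, the gap
# decomposition, and table rendering.

test_that("descriptive statistics match direct recomputation and handle skew", {
  expect_equal(
    descriptive_stats(data.frame(v = c(1, 2, 3)))$skewness, 0,
    tolerance = 1e-12
  )
  x <- c(1, 2, 3, 4, 100)
  ds <- descriptive_stats(data.frame(v = x))
  expect_equal(ds$skewness, skewness_oracle(x), tolerance = 1e-12)
  expect_equal(ds$mean, mean(x))
  expect_equal(ds$min, 1)
  expect_equal(ds$max, 100)
  # constant column: undefined skewness, not zero
  expect_true(is.na(descriptive_stats(data.frame(v = rep(5, 4)))$skewness))
})

test_that("stage specifications add the staged term sets cumulatively", {
  labels <- function(s) {
    vapply(build_stage_spec(s)$terms, function(t) {
      paste(t$column, t$transform)
    }, character(1))
  }
  expect_equal(labels(1), "od_pct log")
  expect_equal(setdiff(labels(2), labels(1)), c("urban_pct identity", "urban_pct square"))
  expect_equal(
    setdiff(labels(3), labels(2)),
    c("mpce log", "calories identity", "cereal_calories identity", "household_size identity")
  )
  expect_equal(
    setdiff(labels(4), labels(3)),
    c("literacy_pct identity", "literacy_female_pct identity")
  )
  expect_true("imr identity" %in% labels(5))
  expect_false("imr identity" %in% labels(4))
  for (s in 2:5) expect_true(all(labels(s - 1) %in% labels(s)))
  expect_equal(build_stage_spec(3)$weights, "population")
  expect_error(build_stage_spec(6), class = "sanistunt_parameter_error")
})

test_that("staged fits: R2 rises with nesting and stage 5 drops IMR-missing rows", {
  d <- suppressMessages(simulate_districts(district_sim_params(seed = 31)))
  sm <- suppressMessages(run_staged_models(d, "stunting_pct"))
  gl <- glance(sm)
  # complete-case nesting across stages 1-4 (same rows): monotone R2
  expect_true(all(diff(gl$r.squared[1:4]) >= -1e-12))
  expect_equal(gl$nobs[1:4], rep(112L, 4))
  expect_equal(gl$nobs[5], 110L) # two districts lack IMR
})

test_that("the stage-1 slope lands within two robust SEs of the structural value", {
  d <- suppressMessages(simulate_districts(district_sim_params(seed = 32)))
  f <- run_staged_models(d, "stunting_pct", stages = 1)$fits[[1]]
  b <- coef(f)["ln(od_pct)"]
  se <- f$std_error["ln(od_pct)"]
  expect_lt(abs(b - 7), 2 * se)
})

test_that("with independent controls the OD slope is stable across stages 1-4", {
  reps <- purrr::map_dfr(1:100, function(i) {
    d <- suppressMessages(simulate_districts(district_sim_params(seed = 7000 + i)))
    sm <- run_staged_models(d, "stunting_pct", stages = c(1, 4))
    tibble::tibble(
      shift = abs(coef(sm$fits[[2]])["ln(od_pct)"] - coef(sm$fits[[1]])["ln(od_pct)"]),
      se1 = sm$fits[[1]]$std_error["ln(od_pct)"]
    )
  })
  expect_lt(mean(reps$shift), mean(reps$se1))
})

test_that("routing part of the OD effect through IMR shrinks the stage-5 slope", {
  falls <- vapply(1:100, function(i) {
    d <- suppressMessages(simulate_districts(
      district_sim_params(mediation_share = 0.3, seed = 8000 + i)
    ))
    sm <- suppressMessages(run_staged_models(d, "stunting_pct", stages = 4:5))
    coef(sm$fits[[2]])["ln(od_pct)"] < coef(sm$fits[[1]])["ln(od_pct)"]
  }, logical(1))
  expect_gte(sum(falls), 90)
})

test_that("marginal effects follow the log-linear prediction", {
  expect_equal(marginal_effect(7.082, 10), 7.082 * log(1.1), tolerance = 1e-12)
  expect_equal(round(marginal_effect(7.082, 10), 1), 0.7)
  expect_equal(marginal_effect(5, 0), 0)
  expect_equal(marginal_effect(11.02, 10), 1.050, tolerance = 5e-4)
  expect_equal(marginal_effect(7.082, 10, method = "log_points"), 0.7082)
  expect_error(marginal_effect(7, -100), class = "sanistunt_parameter_error")
})

test_that("gap shares follow the decomposition formula and are antisymmetric", {
  expect_equal(gap_share(5, 40, 40, 60, 30), 0)
  # unit construction: coefficient equal to the gap, log ratio of 1
  od_hi <- 30
  od_lo <- od_hi * exp(1)
  expect_equal(gap_share(20, od_lo, od_hi, 50, 30), 1, tolerance = 1e-12)
  expect_equal(
    gap_share(11.02, 76.3, 33.8, 59.1, 35.9), 0.387,
    tolerance = 1e-3
  )
  expect_equal(
    gap_share(11.02, 76.3, 33.8, 59.1, 35.9),
    gap_share(11.02, 33.8, 76.3, 35.9, 59.1),
    tolerance = 1e-12
  )
  expect_error(gap_share(5, 40, 30, 50, 50), class = "sanistunt_domain_error")
})

test_that("significance marks use strict thresholds", {
  expect_equal(
    significance_stars(c(0.009, 0.01, 0.04, 0.05, 0.099, 0.10, 0.5)),
    c("**", "*", "*", "†", "†", "", "")
  )
})

test_that("the rendered stage table round-trips its numbers at printed precision", {
  d <- suppressMessages(simulate_districts(district_sim_params(seed = 33)))
  sm <- suppressMessages(run_staged_models(d, "stunting_pct"))
  tab <- format_stage_table(sm)
  # serialize and re-parse as CSV
  withr::with_tempdir({
    readr::write_csv(tab, "table.csv")
    back <- readr::read_csv("table.csv",
      show_col_types = FALSE,
      na = character(), col_types = readr::cols(.default = "c")
    )
    expect_equal(as.data.frame(back), as.data.frame(tab))
  })
  long <- tidy(sm)
  for (s in 1:5) {
    col <- tab[[sprintf("(%d)", s)]]
    est_rows <- tab$row == "estimate" & tab$term == "ln(od_pct)"
    printed <- as.numeric(gsub("[*†]", "", col[est_rows]))
    truth <- long$estimate[long$stage == s & long$term == "ln(od_pct)"]
    expect_equal(printed, signif(truth, 4), tolerance = 1e-12)
    se_rows <- tab$row == "se" & tab$term == "ln(od_pct)"
    printed_se <- as.numeric(gsub("[()]", "", col[se_rows]))
    truth_se <- long$std.error[long$stage == s & long$term == "ln(od_pct)"]
    expect_equal(printed_se, signif(truth_se, 4), tolerance = 1e-12)
  }
  # n and R2 footer rows present for every stage
  expect_equal(tab[[sprintf("(%d)", 5)]][tab$term == "n"], "110")
})

test_that("bivariate district fits report the weighted R2 of a single-predictor model", {
  d <- suppressMessages(simulate_districts(district_sim_params(seed = 34)))
  f <- bivariate_district_fit(d, "stunting_pct", "od_pct")
  expect_equal(names(coef(f)), c("(Intercept)", "od_pct"))
  expect_true(f$r_squared >= 0 && f$r_squared <= 1)
  # matches a direct weighted lm on the same rows
  lmf <- lm(stunting_pct ~ od_pct, data = d, weights = d$population)
  expect_equal(unname(coef(f)), unname(coef(lmf)), tolerance = 1e-8)
})
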