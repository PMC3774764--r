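# District-level synthetic data: one row per district with the outcome
# (stunting prevalence), the exposure (percent of households practicing open
# defecation), the confounder set, and a population weight. The generator
# encodes the structural model the ecological analysis assumes — stunting is
# log-linear in open defecation — so downstream estimators can be checked
# against known truth.

# analytic mean of ln(100 * Beta(a, b))
mean_ln_od <- function(shape) log(100) + digamma(shape[1]) - digamma(sum(shape))

#' Parameters for the district-level generator
#'
#' Defaults emulate the marginal structure of a 112-district Indian sample:
#' stunting prevalence around 56% (severe around 32%), open defecation
#' left-skewed with mean around 70%, infant mortality around 71 per 1,000
#' live births and correlated about 0.47 with ln(open defecation), literacy
#' around 66% (female 56%), monthly per-capita expenditure around 560 rupees,
#' about 2,050 kcal/day of which about 1,400 from cereals, and household size
#' around 6.3.
#'
#' @param n_districts Number of districts (>= 3).
#' @param beta_od Structural effect of `ln(od_pct)` on stunting prevalence,
#'   in percentage points per log-unit. The same slope is used for severe
#'   stunting with a lower intercept.
#' @param control_effects Named numeric vector of structural coefficients for
#'   the (centered) confounders. Recognised names: `urban_pct`,
#'   `urban_pct_sq`, `ln_mpce`, `calories`, `cereal_calories`,
#'   `household_size`, `literacy_pct`, `literacy_female_pct`. Controls are
#'   centered at their realized sample means before entering the outcome, so
#'   effect sizes do not shift the marginal means.
#' @param noise_sd Residual SD of stunting prevalence, in percentage points.
#' @param od_beta_shape Two positive shape parameters; open defecation is
#'   drawn as `100 * Beta(shape1, shape2)`. The default `c(4.8, 2)` gives a
#'   left-skewed distribution (skewness about -0.6) with mean near 70%.
#' @param mean_stunting,mean_severe Target marginal means (percent) of the
#'   two outcomes; they fix the structural intercepts.
#' @param imr_mean,imr_sd Marginal mean and SD of the infant mortality rate.
#' @param imr_od_cor Correlation between IMR and `ln(od_pct)` (default 0.47).
#' @param mediation_share Fraction of the total OD effect routed through IMR
#'   (the early-life disease environment proxy). 0 (default) makes IMR a
#'   correlated non-mediator; positive values make the OD coefficient fall
#'   when IMR is added as a control, at the price of extra outcome noise from
#'   the IMR innovation.
#' @param n_missing_imr Number of districts whose IMR is set missing (the
#'   staged fit then drops them by listwise deletion).
#' @param seed RNG seed stored with the parameters; `NULL` uses the current
#'   RNG stream.
#' @return A `district_sim_params` list.
#' @seealso [simulate_districts()]
#' @export
district_sim_params <- function(n_districts = 112,
                                beta_od = 7,
                                control_effects = c(
                                  urban_pct = 0.2,
                                  urban_pct_sq = -0.005,
                                  ln_mpce = 8,
                                  calories = -0.005,
                                  cereal_calories = 0,
                                  household_size = 1.5,
                                  literacy_pct = -0.8,
                                  literacy_female_pct = 0.3
                                ),
                                noise_sd = 4,
                                od_beta_shape = c(4.8, 2),
                                mean_stunting = 55.9,
                                mean_severe = 31.6,
                                imr_mean = 71.3,
                                imr_sd = 14,
                                imr_od_cor = 0.47,
                                mediation_share = 0,
                                n_missing_imr = 2,
                                seed = NULL) {
  n_districts <- check_count(n_districts, "n_districts", min = 3L)
  check_number(beta_od, "beta_od")
  check_number(noise_sd, "noise_sd", min = 0)
  if (!is.numeric(od_beta_shape) || length(od_beta_shape) != 2L ||
    any(is.na(od_beta_shape)) || any(od_beta_shape <= 0)) {
    abort("`od_beta_shape` must be two positive shape parameters.",
      class = "sanistunt_parameter_error"
    )
  }
  check_number(imr_sd, "imr_sd", min = 0, strict_min = TRUE)
  check_number(imr_od_cor, "imr_od_cor", min = -1, max = 1)
  check_number(mediation_share, "mediation_share", min = 0, max = 1)
  n_missing_imr <- check_count(n_missing_imr, "n_missing_imr", min = 0L)
  if (n_missing_imr >= n_districts) {
    abort("`n_missing_imr` must be smaller than `n_districts`.",
      class = "sanistunt_parameter_error"
    )
  }
  if (mediation_share > 0 && imr_od_cor <= 0) {
    abort("`mediation_share` > 0 requires a positive `imr_od_cor`.",
      class = "sanistunt_parameter_error"
    )
  }
  known <- c(
    "urban_pct", "urban_pct_sq", "ln_mpce", "calories", "cereal_calories",
    "household_size", "literacy_pct", "literacy_female_pct"
  )
  effects <- setNames(rep(0, length(known)), known)
  if (length(control_effects) > 0) {
    bad <- setdiff(names(control_effects), known)
    if (length(bad) > 0) {
      abort(
        sprintf("Unknown control effect(s): %s.", paste(bad, collapse = ", ")),
        class = "sanistunt_parameter_error"
      )
    }
    effects[names(control_effects)] <- control_effects
  }
  structure(
    list(
      n_districts = n_districts, beta_od = beta_od, control_effects = effects,
      noise_sd = noise_sd, od_beta_shape = od_beta_shape,
      mean_stunting = mean_stunting, mean_severe = mean_severe,
      imr_mean = imr_mean, imr_sd = imr_sd, imr_od_cor = imr_od_cor,
      mediation_share = mediation_share, n_missing_imr = n_missing_imr,
      seed = seed
    ),
    class = "district_sim_params"
  )
}

#' Simulate a district-level dataset
#'
#' Draws one row per district. Open defecation is `100 * Beta` (left-skewed by
#' default); stunting prevalence follows the structural model
#' `intercept + beta_od * ln(od_pct) + centered controls + Gaussian noise`,
#' with severe stunting generated with the same slope, a lower intercept and
#' independent noise, floored at 0 and capped at the stunting value. IMR is
#' drawn correlated with `ln(od_pct)`; with `mediation_share > 0` part of the
#' OD effect on both outcomes is carried by the IMR innovation, so
#' conditioning on IMR shrinks the OD coefficient. Population weights are
#' log-normal. Generated percentages are clipped to `[0, 100]`; the number of
#' clipped values is attached as attribute `n_clipped` and reported.
#'
#' @param params A [district_sim_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return A tibble with columns `district_id`, `stunting_pct`,
#'   `severe_stunting_pct`, `od_pct`, `imr`, `urban_pct`, `literacy_pct`,
#'   `literacy_female_pct`, `mpce`, `calories`, `cereal_calories`,
#'   `household_size`, `population`.
#' @examples
#' d <- simulate_districts(district_sim_params(n_districts = 20, seed = 1))
#' dplyr::glimpse(d)
#' @export
simulate_districts <- function(params = district_sim_params(), seed = NULL) {
  if (!inherits(params, "district_sim_params")) {
    abort("`params` must come from `district_sim_params()`.",
      class = "sanistunt_parameter_error"
    )
  }
  if (is.null(seed)) seed <- params$seed
  with_optional_seed(seed, simulate_districts_impl(params))
}

simulate_districts_impl <- function(params) {
  n <- params$n_districts
  eff <- params$control_effects

  od_pct <- 100 * rbeta(n, params$od_beta_shape[1], params$od_beta_shape[2])
  # guard: ln(od) must exist even for extreme shape choices
  od_pct <- pmax(od_pct, 1e-6)
  ln_od <- log(od_pct)

  urban_pct <- 100 * rbeta(n, 1.6, 6.9)
  literacy_pct <- pmin(pmax(rnorm(n, 66.4, 8), 0), 100)
  literacy_female_pct <- pmin(pmax(literacy_pct - rnorm(n, 10.6, 3), 0), literacy_pct)
  mpce <- rlnorm(n, meanlog = log(563) - 0.3^2 / 2, sdlog = 0.3)
  calories <- pmax(rnorm(n, 2056, 200), 1200)
  cereal_calories <- pmin(calories * rbeta(n, 20, 9.2), calories)
  household_size <- pmax(rnorm(n, 6.3, 0.8), 2)
  population <- rlnorm(n, meanlog = log(1.5e6), sdlog = 0.5)

  # IMR correlated with ln(OD): loading rho * sd on the standardized exposure
  z_od <- (ln_od - mean(ln_od)) / sd(ln_od)
  rho <- params$imr_od_cor
  imr_innov <- rnorm(n, 0, params$imr_sd * sqrt(1 - rho^2))
  imr <- params$imr_mean + rho * params$imr_sd * z_od + imr_innov

  # centered controls (realized means) keep Table-style marginals in place
  controls <- cbind(
    urban_pct = urban_pct,
    urban_pct_sq = urban_pct^2,
    ln_mpce = log(mpce),
    calories = calories,
    cereal_calories = cereal_calories,
    household_size = household_size,
    literacy_pct = literacy_pct,
    literacy_female_pct = literacy_female_pct
  )
  controls <- scale(controls, center = TRUE, scale = FALSE)
  control_part <- drop(controls %*% eff[colnames(controls)])

  m <- params$mediation_share
  beta_direct <- (1 - m) * params$beta_od
  # slope of E[imr] in ln(od); beta_imr * alpha = m * beta_od restores the total
  alpha <- rho * params$imr_sd / sd(ln_od)
  beta_imr <- if (m > 0) m * params$beta_od / alpha else 0
  od_part <- beta_direct * ln_od + beta_imr * (imr - params$imr_mean)

  e_lnod <- mean_ln_od(params$od_beta_shape)
  intercept_stunt <- params$mean_stunting - params$beta_od * e_lnod
  intercept_severe <- params$mean_severe - params$beta_od * e_lnod

  stunting_raw <- intercept_stunt + od_part + control_part +
    rnorm(n, 0, params$noise_sd)
  severe_raw <- intercept_severe + od_part + control_part +
    rnorm(n, 0, params$noise_sd)

  n_clipped <- sum(stunting_raw < 0 | stunting_raw > 100) +
    sum(severe_raw < 0 | severe_raw > 100)
  stunting_pct <- pmin(pmax(stunting_raw, 0), 100)
  severe_stunting_pct <- pmin(pmax(severe_raw, 0), stunting_pct)

  if (params$n_missing_imr > 0) {
    imr[sample.int(n, params$n_missing_imr)] <- NA_real_
  }

  out <- tibble(
    district_id = sprintf("D%03d", seq_len(n)),
    stunting_pct = stunting_pct,
    severe_stunting_pct = severe_stunting_pct,
    od_pct = od_pct,
    imr = imr,
    urban_pct = urban_pct,
    literacy_pct = literacy_pct,
    literacy_female_pct = literacy_female_pct,
    mpce = mpce,
    calories = calories,
    cereal_calories = cereal_calories,
    household_size = household_size,
    population = population
  )
  if (n_clipped > 0) {
    inform(sprintf("Clipped %d generated percentage value(s) to [0, 100].", n_clipped))
  }
  attr(out, "n_clipped") <- n_clipped
  attr(out, "true_beta_od") <- params$beta_od
  out
}
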