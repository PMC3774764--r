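# Child-level synthetic data: PSU-clustered records of household open
# defecation and height-for-age z-scores, the input to the dichotomization
# power study. Each PSU (primary sampling unit, the local survey cluster) has
# a latent open-defecation rate; child HAZ declines linearly in that rate.

#' Parameters for the child-level generator
#'
#' Defaults produce about 40,000 children in 2,000 PSUs with mean HAZ near
#' -1.9 and roughly half of children stunted, echoing the scale and anthropo-
#' metric levels of a national Indian child survey.
#'
#' @param n_psu Number of PSUs (>= 2).
#' @param children_per_psu Children per PSU: a single count, or a length-2
#'   range sampled uniformly per PSU.
#' @param delta_haz Change in mean HAZ per unit PSU open-defecation fraction
#'   (expected negative; default -2).
#' @param haz_sd Within-PSU SD of HAZ (> 0; default 1.2).
#' @param intercept_haz Mean HAZ in a PSU with no open defecation.
#' @param od_mean Mean of the Beta distribution of PSU open-defecation rates.
#' @param od_conc Concentration (shape1 + shape2) of that Beta distribution;
#'   smaller values spread PSU rates more widely.
#' @param seed RNG seed stored with the parameters.
#' @return A `child_sim_params` list.
#' @seealso [simulate_children()]
#' @export
child_sim_params <- function(n_psu = 2000,
                             children_per_psu = 20,
                             delta_haz = -2,
                             haz_sd = 1.2,
                             intercept_haz = -0.5,
                             od_mean = 0.7,
                             od_conc = 3,
                             seed = NULL) {
  n_psu <- check_count(n_psu, "n_psu", min = 2L)
  check_number(delta_haz, "delta_haz")
  check_number(haz_sd, "haz_sd", min = 0, strict_min = TRUE)
  check_number(intercept_haz, "intercept_haz")
  check_number(od_mean, "od_mean", min = 0, max = 1)
  check_number(od_conc, "od_conc", min = 0, strict_min = TRUE)
  if (!is.numeric(children_per_psu) || !length(children_per_psu) %in% 1:2 ||
    any(is.na(children_per_psu)) || any(children_per_psu < 1)) {
    abort("`children_per_psu` must be a positive count or a length-2 range.",
      class = "sanistunt_parameter_error"
    )
  }
  children_per_psu <- as.integer(round(children_per_psu))
  structure(
    list(
      n_psu = n_psu, children_per_psu = children_per_psu,
      delta_haz = delta_haz, haz_sd = haz_sd, intercept_haz = intercept_haz,
      od_mean = od_mean, od_conc = od_conc, seed = seed
    ),
    class = "child_sim_params"
  )
}

#' Simulate PSU-clustered child records
#'
#' Each PSU draws an open-defecation rate from
#' `Beta(od_mean * od_conc, (1 - od_mean) * od_conc)`; each child's household
#' indicator is Bernoulli with that rate, and HAZ is Normal with mean
#' `intercept_haz + delta_haz * rate` and SD `haz_sd`.
#'
#' @param params A [child_sim_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return A tibble with columns `psu_id`, `od_household` (0/1), `haz`.
#' @examples
#' kids <- simulate_children(child_sim_params(n_psu = 5, children_per_psu = 3, seed = 1))
#' kids
#' @export
simulate_children <- function(params = child_sim_params(), seed = NULL) {
  if (!inherits(params, "child_sim_params")) {
    abort("`params` must come from `child_sim_params()`.",
      class = "sanistunt_parameter_error"
    )
  }
  if (is.null(seed)) seed <- params$seed
  with_optional_seed(seed, simulate_children_impl(params))
}

simulate_children_impl <- function(params) {
  n_psu <- params$n_psu
  shape1 <- params$od_mean * params$od_conc
  shape2 <- (1 - params$od_mean) * params$od_conc
  rate <- rbeta(n_psu, shape1, shape2)
  sizes <- if (length(params$children_per_psu) == 1L) {
    rep(params$children_per_psu, n_psu)
  } else {
    sample(params$children_per_psu[1]:params$children_per_psu[2], n_psu, replace = TRUE)
  }
  psu_id <- rep(sprintf("P%05d", seq_len(n_psu)), times = sizes)
  rate_child <- rep(rate, times = sizes)
  n_children <- length(rate_child)
  tibble(
    psu_id = psu_id,
    od_household = rbinom(n_children, 1L, rate_child),
    haz = rnorm(n_children, params$intercept_haz + params$delta_haz * rate_child,
      sd = params$haz_sd
    )
  )
}

#' Analytic mean HAZ implied by child-generator parameters
#'
#' `intercept_haz + delta_haz * od_mean`, the population mean against which
#' large-sample output can be checked.
#'
#' @param params A [child_sim_params()] object.
#' @return A single number.
#' @export
expected_mean_haz <- function(params) {
  params$intercept_haz + params$delta_haz * params$od_mean
}
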