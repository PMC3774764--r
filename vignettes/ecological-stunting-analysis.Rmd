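---
title: "Ecological regression of open defecation and child stunting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological regression of open defecation and child stunting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanistunt)
library(dplyr)
```

## The problem

Childhood stunting — a height-for-age z-score (HAZ) more than two standard
deviations below the reference median — remains widespread in India even as
incomes and calorie availability improve. One candidate explanation is the
early-life disease environment produced by open defecation (OD): repeated
enteric infection diverts energy from growth. Individual-level height data
linked to sanitation are scarce, so the question is often attacked
*ecologically*: regress district-level stunting prevalence on district-level
OD prevalence, adjusting for observable confounders. This package implements
that pipeline — estimator, transformation selection, staged adjustment,
effect summaries — together with a Monte Carlo study of a second
methodological question: how much statistical power is lost when continuous
height data are dichotomized into stunting indicators before analysis.

Because the underlying district tables are published aggregates rather than
downloadable microdata, the package ships seeded generators that emulate
their statistical structure. Every estimator is therefore testable against
known truth, end to end.

## The district-level model

For districts $i = 1, \dots, n$ the working model is

$$\text{stunting}_i \;=\; \alpha + \beta \,\ln(\text{OD}_i) + \gamma' z_i + \varepsilon_i,$$

estimated by weighted least squares with district population as an analytic
weight and heteroscedasticity-robust (sandwich) standard errors. Adjustment
is staged so the stability of $\beta$ is visible:

1. $\ln(\text{OD})$ alone;
2. add urban share as a quadratic in the raw percentage (urban households
   rarely practice OD, and urbanization correlates with much else);
3. add economic controls: log monthly per-capita expenditure, calories per
   capita, cereal calories per capita, household size;
4. add overall and female literacy;
5. add the infant mortality rate (IMR). Stage 5 is deliberately
   *mis*-specified: IMR proxies the same latent disease environment that OD
   is hypothesized to act through, so if the mechanism is real, conditioning
   on IMR should pull $\beta$ toward zero rather than leave it unchanged.

Implementation choices worth stating:

- **Analytic weights.** Weights are rescaled internally to sum to $n$, so
  estimates, standard errors and the weighted $R^2$ are invariant to the
  scale of the population column. This matches the weighted-regression
  semantics of the major survey-analysis packages.
- **Robust variant.** "Heteroscedasticity-robust" does not pin down a
  finite-sample correction; the default here is HC1
  (meat scaled by $n/(n-k)$), the default of the software ecosystem this
  kind of analysis is usually run in, with HC0/HC2/HC3 and classical
  covariances available via `se_type`.
- **Missing data.** Listwise deletion per model, with the dropped count
  reported; with the default generator two districts lack IMR, so stage 5
  runs on $n-2$ districts while stages 1–4 keep all $n$.
- **Inference.** $t$-based with $n - k$ degrees of freedom (intercept
  included in $k$). Significance marks use strict thresholds: `**` for
  $p < 0.01$, `*` for $p < 0.05$, a dagger for $p < 0.10$; $p = 0.10$
  exactly earns no mark.
- **Quadratic term.** Built from the raw percentage, not centered — the
  printed coefficient scale of published tables of this kind corresponds to
  the raw polynomial, and collinearity between the linear and squared terms
  is harmless for the fitted surface.

## Choosing the exposure transformation

There is no a-priori reason for stunting to be linear in OD percentage
points; percentage-point changes at 90% OD plausibly matter less than at
20%. The transformation is selected by profiling a Box-Cox family on the
*exposure*:

$$x^{(\lambda)} = \frac{x^\lambda - 1}{\lambda}, \qquad x^{(0)} = \ln x.$$

The textbook Box-Cox procedure transforms the outcome and needs a Jacobian
term in the likelihood; transforming a regressor does not. For each
$\lambda$ the outcome is regressed on $x^{(\lambda)}$ (plus any covariates)
and the concentrated Gaussian log-likelihood
$\ell(\lambda) = -\tfrac{n}{2}\left(1 + \ln\frac{2\pi\,\mathrm{RSS}(\lambda)}{n}\right)$
is recorded. The estimate maximizes $\ell$ over a coarse grid (default
$[-3, 3]$ in steps of 0.05, wide enough to bracket any plausible candidate)
refined by golden-section search to $10^{-6}$; the 95% confidence interval
inverts the likelihood-ratio test, i.e. collects the $\lambda$ with
$\ell(\lambda) \ge \ell(\hat\lambda) - \chi^2_{1,0.95}/2 \approx
\ell(\hat\lambda) - 1.92$, found by root-finding on each side. If the
profile never drops below the cutoff inside the search bounds the interval
is truncated there with a warning. LR tests against $\lambda \in \{-1, 0,
1\}$ are reported by default.

Two caveats are recorded in the fitted object rather than hidden:
$\hat\lambda$ is *not* invariant to rescaling the exposure (the percent
scale is part of the definition), and whether the profile regression should
carry the population weights is genuinely ambiguous — the default is
unweighted with a `weights` option, since the likelihood being profiled is
an unweighted Gaussian one.

On synthetic districts generated with a log-linear OD effect, the profile
behaves exactly as the method predicts: the CI covers 0, LR tests reject
$\pm 1$, and on data generated linear in the exposure the CI covers 1
instead. That is the basis of the recovery tests.

## Effect summaries

With stunting linear in $\ln(\text{OD})$, a proportional increase of $p$%
in OD changes predicted prevalence by $\beta \ln(1 + p/100)$ percentage
points (`marginal_effect()`; the additive log-point approximation
$\beta\,p/100$ is exposed as `method = "log_points"` — for $p = 10$ both
round to the same first decimal).

For two district groups (conventionally a high-stunting "low-performing"
group and a low-stunting "high-performing" one), the share of the stunting
gap statistically attributable to the OD difference is

$$\text{share} = \frac{\beta\,[\ln(\text{OD}_{\text{low}}) - \ln(\text{OD}_{\text{high}})]}{\text{stunting}_{\text{low}} - \text{stunting}_{\text{high}}}.$$

A known wrinkle: applied to the published group means (stunting 59.1% vs
35.9%, OD 76.3% vs 33.8%) with the published bivariate and fully adjusted
coefficients (11.02 and 7.082 pp per log-unit), this formula yields shares
of about 39% and 25%, whereas the source narrative quotes "35 to 55
percent" for the same construction. The decomposition arithmetic behind the
published range is not stated anywhere we can check, so the formula is
implemented as written and the discrepancy documented rather than patched.

## The dichotomization power study

The HUNGaMA-style district tables report only dichotomized stunting rates,
not mean heights. To quantify what that costs, `run_power_study()` runs the
following Monte Carlo on PSU-clustered child records (PSU = primary
sampling unit, the local survey cluster):

1. draw a simple random sample of `sample_size` children **without
   replacement** (the sampling scheme is stated as "simple random sample";
   replacement policy is our documented choice);
2. collapse the sample to PSU means: OD fraction, mean HAZ, fraction
   stunted (HAZ $< -2$, strict), fraction severely stunted (HAZ $< -3$);
3. regress each of the three collapsed outcomes on the PSU OD fraction by
   unweighted OLS (no weights are indicated for this step; weighting by PSU
   sample size is available as an option, and PSUs with at least one
   sampled child enter by default, configurable via `min_psu_n`);
4. record slope, $t$, $R^2$; repeat.

The summary is a pair of *win fractions*: the share of replicates in which
the continuous (mean-HAZ) regression's $R^2$ strictly exceeds both
dichotomized $R^2$s, and likewise for $|t|$ — absolute value, because the
continuous slope is negative while the stunting-fraction slopes are
positive. At the default study scale (200 replicates of 20,000 children
from 2,000 PSUs of ~20 children, effect $-2$ HAZ per unit OD fraction,
within-PSU SD 1.2) both win fractions are at or near 1: dichotomization
discards information whenever the threshold is not where the action is.

One regime deserves a note: the power gap is *not* monotone in effect size
everywhere. When the effect is so large that PSU mean HAZ values center on
the $-2$ cutoff, the binary indicator becomes maximally responsive and the
race tightens; the monotone "bigger effect, bigger continuous advantage"
property holds in the weak-to-moderate regime, which is where the question
matters, and the test suite exercises exactly that regime. In the limit
where HAZ is a deterministic step of the PSU OD rate across the cutoff,
dichotomized and continuous $R^2$ coincide — dichotomization loses nothing
precisely when the indicator captures all the variation — and a test pins
that equivalence.

## What the generators emulate — and what they do not

**Districts** (`simulate_districts()`). One row per district with the full
column contract. Defaults were fixed once, from the published descriptive
marginals, before any downstream checks:

- OD is $100 \times \mathrm{Beta}(4.8, 2)$: mean ≈ 70.6%, left-skewed
  (skewness ≈ $-0.6$). The published sample skewness of $-2.0$ is *not*
  reachable by any Beta with mean 0.705 (the Bernoulli limit for that mean
  is $-0.9$); the Beta family reproduces the qualitative left skew while
  keeping the mean and range right, and the tests assert skewness
  $< -0.5$, not the unreachable value.
- Stunting follows the structural model
  $\alpha + 7\ln(\text{OD}) + \gamma'(z - \bar z) + \mathcal N(0, 4^2)$,
  with the intercept set so the mean is 55.9%. Controls enter centered at
  their realized means, so structural effect sizes do not move the
  marginal means; centering only shifts the intercept, so fitted slopes
  still recover the generator coefficients. Severe stunting uses the same
  slope with a lower intercept (mean 31.6%), independent noise, floored at
  0 and capped at the stunting value — the sources give no joint model, so
  the cap is the whole joint structure. Out-of-range values are clipped to
  $[0, 100]$ and the clip count attached as an attribute.
- IMR is drawn with correlation 0.47 with $\ln(\text{OD})$ (mean 71.3, SD
  14), and a configurable number of districts (default 2) have IMR set
  missing. With `mediation_share` $= m > 0$, a fraction $m$ of the OD
  effect is routed through the IMR innovation, so conditioning on IMR
  shrinks the OD coefficient — the stage-5 pattern. The default is $m = 0$
  so that the noiseless generator is exactly log-linear (a property the
  tests rely on); the mediation tests set $m = 0.3$, which at the default
  scales produces a stage-4 → stage-5 fall in well over 90% of samples.
- Controls are mutually independent by default. The published tables give
  marginals only; the joint correlation structure is a free choice, and
  independence is the one choice that makes the "coefficient stable across
  stages 2–4" property literally true in the generator, which is what the
  robustness tests check. Real confounding would move the staged
  coefficients more than these tests allow; that is a statement about the
  generator, not about real districts.

**Children** (`simulate_children()`). PSU OD rates are
$\mathrm{Beta}(2.1, 0.9)$ (mean 0.7); each child's household indicator is
Bernoulli with the PSU rate, and HAZ is
$\mathcal N(-0.5 - 2\,\text{rate},\ 1.2^2)$. With ~20 children in each of
2,000 PSUs this gives ≈ 40,000 children with mean HAZ ≈ $-1.9$ and ≈ 48%
stunted — the scale and levels of a national child anthropometry survey.
Not emulated: survey stratification and sampling weights, age structure
within the under-5 range, within-household correlation, and measurement
error in recorded heights. Passing tests therefore demonstrate that the
estimators do what they claim on data with the assumed structure; they do
not demonstrate anything about residual confounding in real aggregates.

## Problem sizes

The test suite and the reproduction script use: 100 synthetic district
samples of $n = 112$ for slope-CI coverage and for the mediation pattern;
$n = 500$, noise SD 2 for transformation recovery (10 seeded datasets per
generating transform); and 200 power-study replicates of 20,000 children
drawn from ≈ 40,000. These sizes give stable Monte Carlo summaries (win
fractions and coverage counts move by a point or two across seeds) while
the whole suite runs in well under a minute.

## A worked run

```{r worked, eval = FALSE}
d <- simulate_districts(district_sim_params(seed = 1))
descriptive_stats(d)

fits <- run_staged_models(d, "stunting_pct")
glance(fits)
format_stage_table(fits)

estimate_boxcox_lambda(d, "stunting_pct", "od_pct")

kids <- simulate_children(child_sim_params(seed = 2))
ps <- run_power_study(kids, sample_size = 20000, n_reps = 200, seed = 3)
glance(ps)
autoplot(ps)
```

## Known limitations

- The ecological design itself: district-level association, even robust to
  the staged controls, is not an individual-level or causal estimate, and
  the generator's independence defaults make the staged-stability tests a
  best case.
- The Box-Cox CI relies on the $\chi^2_1$ asymptotics of the LR statistic;
  at $n$ far below the ~100-district scale the interval is approximate.
- `gap_share()` implements the stated decomposition formula; as documented
  above, the published "35 to 55 percent" range for the same inputs cannot
  be reproduced from that formula and is not a target of any test.
- The power study treats the PSU rate as the only driver of HAZ; real
  clustered height data have household- and child-level covariance the
  generator omits, so real win fractions need not equal the synthetic ones
  (the published simulation on real survey microdata found 955/1,000 for
  $R^2$; the synthetic defaults give values at or near 200/200).
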