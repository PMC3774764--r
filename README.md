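# sanistunt

District-level ecological regression of child stunting on open defecation,
and a Monte Carlo study of the statistical power lost by dichotomizing child
height — with seeded synthetic-data generators so the whole pipeline is
testable without any external data.

## Who this is for

Epidemiologists and quantitative social scientists working with published
*aggregate* anthropometry: district tables that report the percent of
children stunted (height-for-age z-score, HAZ, below −2) and severely
stunted (below −3), alongside census-style covariates. The package
implements the standard analysis for asking whether sanitation — the
percent of households practicing open defecation (OD) — predicts stunting
prevalence across districts after staged confounder adjustment, plus the
methodological sidebar such data force on you: stunting indicators are
dichotomized height, and dichotomization costs power.

## The model

For districts $i = 1,\dots,n$, weighted least squares with population
analytic weights and heteroscedasticity-robust (HC1 sandwich) standard
errors:

$$\text{stunting}_i = \alpha + \beta\,\ln(\text{OD}_i) + \gamma' z_i + \varepsilon_i$$

Controls $z$ enter in five cumulative stages: none; urban share (quadratic);
log expenditure, calories, cereal calories, household size; overall and
female literacy; infant mortality rate (IMR — a probe of the early-life
disease-environment mechanism, not a confounder). The log transform of OD
is not assumed: it is selected by profiling a Box-Cox family
$x^{(\lambda)} = (x^\lambda - 1)/\lambda$ on the exposure with a
concentrated Gaussian likelihood, with a likelihood-ratio 95% CI for
$\lambda$.

The power study draws repeated subsamples of PSU-clustered child records,
collapses them to PSU (primary sampling unit) means, regresses mean HAZ,
fraction stunted, and fraction severely stunted on the PSU OD fraction, and
reports the share of replicates in which the continuous outcome beats both
dichotomized ones on $R^2$ and on $|t|$.

## Worked example

```r
library(sanistunt)

d <- simulate_districts(district_sim_params(seed = 7))   # 112 districts
descriptive_stats(d)
#> # A tibble: 12 × 6
#>   variable                n  mean   min   max skewness
#>   <chr>               <int> <dbl> <dbl> <dbl>    <dbl>
#> 1 stunting_pct          112  55.2  39.1  77.0   -0.169
#> 2 severe_stunting_pct   112  31.5  16.8  50.6    0.297
#> 3 od_pct                112  68.0  26.1  94.8   -0.365
#> 4 imr                   110  70.6  37.1 119.     0.300
#> # ℹ 8 more rows

fits <- run_staged_models(d, "stunting_pct")
glance(fits)
#> # A tibble: 5 × 6
#>   stage r.squared df.residual  nobs n.dropped se.type
#>   <int>     <dbl>       <int> <int>     <int> <chr>
#> 1     1    0.0564         110   112         0 HC1
#> 2     2    0.130          108   112         0 HC1
#> 3     3    0.259          104   112         0 HC1
#> 4     4    0.708          102   112         0 HC1
#> 5     5    0.709           99   110         2 HC1

dplyr::filter(tidy(fits), term == "ln(od_pct)")
#> # A tibble: 5 × 7
#>   stage stars term       estimate std.error statistic  p.value
#>   <int> <chr> <chr>         <dbl>     <dbl>     <dbl>    <dbl>
#> 1     1 †     ln(od_pct)     6.01      3.12      1.93 0.0562
#> 2     2 *     ln(od_pct)     6.04      2.77      2.19 0.0310
#> 3     3 *     ln(od_pct)     7.13      2.84      2.51 0.0137
#> 4     4 **    ln(od_pct)     6.55      1.78      3.69 0.000363
#> 5     5 **    ln(od_pct)     7.61      2.07      3.67 0.000387
```

The generator's structural slope is 7 pp of stunting per log-unit of OD;
the staged estimates hover around it (controls are independent by default,
so adjustment changes the coefficient only by noise), `nobs` drops to 110
at stage 5 because two districts lack IMR, and `format_stage_table(fits)`
renders the journal-style table with standard errors in parentheses and
strict-threshold significance marks.

Effect summaries work on any coefficient, including published ones. With a
fully adjusted coefficient of 7.082 pp per log-unit:

```r
marginal_effect(7.082, pct_increase = 10)   # a 10% proportional rise in OD
#> [1] 0.6749867                              # ~0.7 pp more stunting
gap_share(7.082, od_low_pct = 76.3, od_high_pct = 33.8,
          stunting_low_pct = 59.1, stunting_high_pct = 35.9)
#> [1] 0.2485453                              # ~25% of the 23.2 pp gap
```

The dichotomization power study, at study scale (≈40,000 children, 2,000
PSUs, 200 subsamples of 20,000):

```r
kids <- simulate_children(child_sim_params(seed = 2))
ps <- run_power_study(kids, sample_size = 20000, n_reps = 200, seed = 3)
glance(ps)
#> # A tibble: 1 × 4
#>   r2_win_fraction abs_t_win_fraction n_reps sample_size
#>             <dbl>              <dbl>  <int>       <int>
#> 1               1                  1    200       20000
autoplot(ps)   # overlaid R² histograms; the continuous outcome sits right
```

In every one of the 200 replicates the continuous mean-HAZ regression
out-explains both dichotomized versions — dichotomizing height discards
information.

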