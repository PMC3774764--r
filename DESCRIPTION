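Package: sanistunt
Title: Ecological Regression of Open Defecation and Child Stunting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for district-level ecological regression of child stunting
    prevalence on open defecation and staged confounder adjustment: weighted
    least squares with heteroscedasticity-robust (sandwich) standard errors,
    maximum-likelihood Box-Cox selection of the exposure transformation with
    likelihood-ratio confidence intervals, marginal-effect and gap-share
    summaries, and a Monte Carlo study of the statistical power lost by
    dichotomizing continuous height-for-age z-scores into stunting
    indicators. Includes seeded synthetic-data generators that emulate the
    district-level and child-level survey structure the analysis assumes, so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
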