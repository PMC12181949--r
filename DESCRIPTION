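Package: smokeburden
Title: Smoke-Stratified PM2.5 Health Burden Estimation and Prescribed-Fire
    Scenario Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for attributing cardiorespiratory emergency-department
    visit burden to all-source fine particulate matter (PM2.5) on
    smoke-stratified days, and for projecting that burden onto a
    hypothetical future prescribed-fire scenario. Provides a seeded
    synthetic ZIP-day panel generator, smoke-day and concentration-strata
    classification with person-day exposure accounting, distributed-lag
    Poisson health impact functions with BIC lag selection, strata-specific
    attributable burden rates, a zero-smoke counterfactual, and the
    historical-versus-future difference-in-difference comparison of annual
    prescribed-fire-attributed burden rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
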