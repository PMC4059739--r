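Package: poolhaz
Title: Carcinogenesis Modelling for Populations with Dichotomous Cancer Susceptibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Top-down carcinogenesis modelling for populations in which only a
    small susceptible pool of individuals can ever develop a given cancer.
    Estimates the susceptible-pool fraction from age-specific incidence data,
    inverts the observed population hazard rate to the hazard rate of a
    susceptible individual with propagated standard errors, fits a
    three-parameter Weibull (multistage) hazard to the individual rate, and
    predicts stratified population hazard curves including their old-age
    turnover. Ships reference pancreatic cancer hazard tables (SEER 9,
    1975-2004; six population strata) and a synthetic cohort simulator for
    end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
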