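Package: stburden
Title: Lifetime Health and Economic Burden of Smokeless Tobacco Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A prevalence-based Markov state-transition cohort model that
    estimates the lifetime healthcare costs, life years and disability-adjusted
    life years (DALYs) attributable to smokeless tobacco use, by 5-year age-sex
    cohorts, under the current pattern of use versus a counterfactual in which
    no smokeless tobacco is consumed. Tunnel states track years since quitting
    so that disease and mortality risks, and the probability of relapse, decay
    with time since cessation. Includes calibration of annual initiation and
    quit probabilities from cross-sectional banded prevalence, apportionment of
    population disease prevalence and mortality across exposure classes by
    relative risks, DALY and cost accounting with discounting, Monte Carlo
    probabilistic sensitivity analysis, and a synthetic country-bundle
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    readr,
    jsonlite,
    stats,
    ggplot2,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
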