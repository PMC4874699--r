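Package: wolfpolicy
Title: Bayesian State-Space Analysis of Culling-Policy Signals in Wolf Population Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian state-space modelling of recovering grey
    wolf populations observed through imperfect annual minimum and maximum
    counts in two replicate states. Population growth rate is modelled as a
    linear function of a policy signal (the proportion of each wolf-year in
    which culling was legally allowed), with known culling removals entering
    through an additivity multiplier, lognormal process error, and
    Poisson-Gamma count observation layers. Includes a policy-timeline
    module converting dated authority periods into the signal covariate,
    three density-dependence side-models (pack size, pack reproduction,
    occupied area), a self-contained blocked adaptive random-walk Metropolis
    sampler with an Rcpp core, Gelman-Rubin and Heidelberger-Welch
    convergence diagnostics, a synthetic-data generator for parameter
    recovery and calibration studies, and tidy reporting of derived policy
    quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
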