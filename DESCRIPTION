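Package: demsoc
Title: Social Evolution Under Demographic Stochasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how demographic stochasticity shapes the
    evolution of indiscriminate social traits (altruism and spite) in
    well-mixed populations of fluctuating size. Provides a library of
    two-type birth-death-mutation models (social actions on death or birth
    rates), exact Gillespie simulation of the individual-based process, the
    slow-timescale diffusion reduction for the actor frequency with its
    drift and noise coefficients, stationary distributions of the frequency
    diffusion (general quadrature and closed forms), the turnover-to-size
    ratio decomposition, favourability and selective-reversal analyses,
    optimal social-action strength, and Euler-Maruyama integration of the
    frequency and multi-type density stochastic differential equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
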