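Package: evorescue
Title: Eco-Evolutionary Predator-Prey Dynamics and Evolutionary Rescue Under Climate Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled daily-timestep simulation of an aphid-ladybird
    predator-prey system in a seasonally varying, warming climate. Vital
    rates follow thermal performance curves whose optimum is an evolving
    quantitative trait; selection acts on discretized breeding-value
    distributions and additive genetic variance follows Bulmer's
    infinitesimal-model recursion, with contrasting life histories
    (continuous sexual reproduction for the predator, a long asexual
    phase with one annual sexual generation and inbreeding for the prey).
    Includes a three-parameter smoothed climate generator and fitter,
    photoperiod-driven phenology, scenario drivers (stable climate,
    climate change without evolution, full eco-evolutionary model),
    seasonality/trend manipulation experiments, genetic-variance
    sensitivity analyses, and an individual-based Monte Carlo oracle for
    validating the deterministic integral updates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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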