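Package: gutsim
Title: Multicompartmental Gastrointestinal Drug Absorption Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates oral drug absorption through a multicompartmental
    model of the gastrointestinal tract: Noyes-Whitney tablet dissolution in
    the stomach with Henderson-Hasselbalch pH-dependent solubility, discrete
    gastro-duodenal emptying events on a fixed cadence, a train of chyme
    boluses transiting the jejunum and ileum-colon while exchanging drug with
    a countercurrent splanchnic blood chain, and a delayed peripheral
    circulation compartment with first-order elimination. Includes
    three-parameter nonlinear least-squares estimation from observed
    concentration-time curves, dose-extrapolation prediction, effective
    intestinal permeability computation, packaged drug property fixtures, and
    a synthetic-observation generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
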