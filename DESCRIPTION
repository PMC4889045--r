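Package: extrande
Title: Exact Stochastic Simulation of Reaction Networks in Dynamic Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conditionally exact stochastic simulation of biomolecular
    reaction networks whose propensities vary in time under exogenous,
    pre-simulated inputs. Implements the Extrande thinning algorithm
    (extra-reaction-channel rejection sampling with a look-ahead propensity
    bound), together with two reference methods for comparison: the slow
    input approximation (SIA) and the modified next reaction method with
    trapezoidal propensity integration. Ships generators for common input
    processes (circadian sinusoid, Ornstein-Uhlenbeck noise, normalized
    lognormal and modulated circadian rates), analytic and numerical oracles
    (conditional moment ODEs, finite-state integration of the chemical
    master equation), error metrics, and an ensemble layer for cell-fate
    experiments such as quorum-sensing competence decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
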