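Package: adaptcrt
Title: Simulation of Bayesian Multi-Arm Multi-Stage Cluster Randomised Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-arm multi-stage (MAMS) cluster randomised
    controlled trials with clustered binary outcomes, fits a Bayesian
    hierarchical logistic model at interim and final analyses via a
    Polya-Gamma Gibbs sampler, applies arm-dropping and futility-stopping
    rules based on the posterior probability of each arm being best, and
    estimates operating characteristics (power, type 1 error, null-calibrated
    scaled power, decision frequencies, sample size) over factorial grids of
    trial properties. Includes a case study comparing sequential two-arm,
    fixed four-arm, and adaptive four-arm designs for implementation-strategy
    optimisation trials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
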