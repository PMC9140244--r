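Package: cnvsbi
Title: Simulation-Based Inference of CNV Formation Rate and Fitness from
    Adaptation Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulators and likelihood-free inference for the
    population dynamics of a focal class of beneficial mutations (copy
    number variants) in asexual populations. Provides a discrete-generation
    Wright-Fisher simulator and a continuous-time stochastic chemostat
    simulator (Monod growth, tau-leaping), two inference engines (sequential
    Monte Carlo approximate Bayesian computation, and amortized neural
    posterior estimation with a hand-implemented conditional density
    estimator), posterior assessment tools (KDE-based MAP, highest density
    regions and intervals, posterior predictive checks, AIC/WAIC), inference
    of a Gamma distribution of fitness effects from replicated experiments,
    effective population size estimation, and synthetic benchmark data
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
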