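Package: pathMPC
Title: Three-Timescale Pathway Simulation and Surrogate Model-Predictive
    Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates integrated gene-regulatory, signaling and metabolic
    networks as a stiff three-timescale ODE system with modified
    Michaelis-Menten and mass-action rate laws, provides quasi-steady-state
    reductions and equilibrium-input solving, and wraps the simulator as a
    MIMO plant. A sliding-window dataset generator feeds an ensemble of
    epsilon-insensitive support vector regression surrogates, and a genetic
    algorithm acts on the surrogate as a model-predictive controller that
    drives selected outputs to reference setpoints. Ships a curated
    central-carbon-metabolism network with Warburg-effect, cancer-control
    and drug-target scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    kernlab,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
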