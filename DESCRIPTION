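Package: structplast
Title: Stochastic Structural Plasticity on Multi-Synaptic Connections
Version: 0.1.0
Authors@R:
    person("Martin", "Keller", email = "mkeller.neuro@posteo.net", role = c("aut", "cre"))
Description: Models the interaction between rate-based synaptic plasticity and
    stochastic, weight-dependent structural plasticity on a single connection
    between two neurons. Provides the birth-death Markov chain over synapse
    counts with its exact transition matrix and first-step (detailed-balance)
    stationary distribution, a six-case classification of equilibrium
    distribution shapes, condition checkers that decide whether a plasticity
    rule can produce experimentally observed bimodal synapse-count
    distributions, event-driven integration of a calcium-threshold spiking
    plasticity rule, an adaptive exponential integrate-and-fire f-I curve,
    full time-stepped stochastic simulation including a hysteresis protocol,
    and Monte-Carlo goodness-of-fit comparison against sparse experimental
    synapse-count histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
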