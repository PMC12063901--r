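Package: parsyn
Title: Parallel-Synapse Neuron Models and Classification Capacity
Version: 0.1.0
Authors@R:
    person("Parsyn", "Developers", email = "parsyn@example.org", role = c("aut", "cre"))
Description: Models of a single neuron whose presynaptic axons each make
    several nonlinear (sigmoidal) synaptic contacts in parallel. Provides a
    restricted neuron with a fixed number M of learnable sigmoidal synapses
    per axon trained by hinge-loss gradient descent, an unrestricted neuron
    whose per-axon transmission is an arbitrary monotone staircase fit by a
    convex-minorant (weighted isotonic) envelope solver with iterative
    importance reweighting, a sign-constrained perceptron baseline, the full
    classification-capacity estimation protocol on random patterns (success
    grids, logistic interpolation of the 50% crossing, resampling confidence
    intervals), post-training synapse diagnostics, and a small feedforward
    network extension with a parallel-synapse layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
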