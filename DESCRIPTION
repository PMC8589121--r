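Package: spikedim
Title: Generalizability of STDP-Trained Spiking Neural Networks via
    Heavy-Tail Analysis of Learning Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulation of two-layer conductance-based
    leaky integrate-and-fire networks trained with spike-timing-dependent
    plasticity (additive, multiplicative, and logarithmic rules), Poisson
    rate coding of images, and a test-set-independent generalizability
    measure built on the Blumenthal-Getoor index of the synaptic weight
    trajectory: per-layer tail indices of weight-update increments are
    estimated with a block log-moment estimator and their maximum bounds
    the Hausdorff dimension of the learning path. Includes an alpha-stable
    process toolkit (Chambers-Mallows-Stuck sampling, Levy-driven
    Ornstein-Uhlenbeck simulation, a jump-driven membrane SDE), Gaussian
    kernel density estimation of weight distributions, and sequential
    model-based Bayesian optimization of STDP hyperparameters with a
    Gaussian-process surrogate and expected-improvement acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
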