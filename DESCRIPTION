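Package: valdec
Title: Reinforcement-Learning Decoders for Economic Value Signals in
    Primate Prefrontal Spike Trains
Version: 0.1.0
Authors@R:
    person("Value Decoding", "Maintainers", email = "valdec@example.org",
           role = c("aut", "cre"))
Description: Tools for building and interrogating adaptive neural decoders
    that read out economic-value-based choices from multivariate spike-count
    time series, as recorded in orbitofrontal cortex (OFC) during
    two-alternative value-guided decision tasks.  Provides a synthetic
    generator of value-coding sessions with known ground truth, offline
    deep Q-learning over three step-based decision environments, a
    transformer-encoder Q-decoder with Boltzmann exploration, a
    stimulus-conditioned stochastic recurrent forecaster of neural activity,
    supervised baselines (radial-basis kernel classifier, recurrent network),
    Shapley-style temporal attribution, and ensemble decomposition of
    predictive uncertainty into aleatoric and epistemic components.  All
    neural-network primitives are implemented natively (RcppArmadillo) with
    exact, finite-difference-verified gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
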