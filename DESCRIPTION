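Package: cardexplore
Title: Uncertainty-Guided Exploration in a Two-Deck Card Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and model-based analysis of exploratory choice in an
    incremental learning task with four tables of paired card decks. Provides
    a conjugate Beta-Bernoulli Bayesian observer over the sign of the deck
    proportion difference (posterior probability by adaptive quadrature,
    entropy, expected information gain, exposure), strategy-driven agent
    simulation of complete study datasets, penalized logistic choice models
    with cross-validated strategy comparison and model recovery, a piecewise
    logistic model with a free overall-uncertainty threshold quantifying
    uncertainty approach versus avoidance, and test-phase validation of the
    observer model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
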