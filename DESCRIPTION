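Package: cogrnn
Title: Tiny Recurrent Networks and Cognitive Models for Trial-by-Trial Choice Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators for classic reward-learning tasks (reversal learning,
    two-stage bandits, drifting bandits and a meta reinforcement-learning
    environment), a catalogue of classical cognitive models (Bayesian
    inference, model-free and model-based reinforcement learning and their
    variants), and tiny gated recurrent unit (GRU) choice models with one to
    twenty units. Models are fitted to trial-by-trial choice data by maximum
    likelihood under nested cross-validation, group knowledge is transferred
    to individual-subject models by knowledge distillation, and any fitted
    model can be interpreted as a discrete dynamical system through phase
    portraits, fixed points, preference setpoints and dynamical regression.
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
    withr
Config/testthat/edition: 3
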