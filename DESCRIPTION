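Package: neurongame
Title: Simulation and Analysis of Group Coordination by Neuron-Like Binary Decision Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a sensorimotor group-coordination game in which eight
    neuron-like binary decision units, each with a hidden movement direction,
    jointly steer a cursor to targets, and analyses the resulting behaviour.
    Four decision models generate unit behaviour: Bayesian expected utility
    over a von Mises belief, Thompson sampling from the same belief, SARSA
    with eligibility traces over tile-coded features, and an online
    perceptron. A metrics suite quantifies cooperation (success rates,
    counterfactual correct-response rates, event synchronization, action-time
    correlation, a covariance-based cooperation measure) and learning
    (spike-triggered average and variance, learning duration,
    population-vector decoding error, cumulative-exponential learning-curve
    fits). Includes event-log file formats, a generator of human-style
    millisecond press logs, and a hyperparameter calibration harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
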