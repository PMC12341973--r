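Package: bcrnn
Title: Bayesian Chemical Reaction Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of mass-action chemical reaction networks from
    time-resolved species concentration data, with uncertainty
    quantification. A chemical reaction neural network (CRNN) -- a
    one-hidden-layer network whose input weights are reaction orders,
    biases are log rate constants, and output weights are net
    stoichiometric coefficients -- is embedded as the right-hand side of
    a neural ordinary differential equation and trained by preconditioned
    stochastic gradient Langevin dynamics (pSGLD). Samples of the network
    weights collected after the loss stagnates form a posterior over
    reaction networks, from which reactant recovery probabilities, score
    metrics, rate-constant posteriors and posterior-predictive trajectory
    fans are derived. Includes a synthetic-data generator for two
    benchmark systems, a plain-SGLD training mode, and two purely
    data-driven baselines (an unconstrained dense neural ODE and an LSTM
    sequence model) for extrapolation comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
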