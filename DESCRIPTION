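Package: twostepAI
Title: Active Inference and Hybrid Reinforcement Learning Models for the
    Two-Step Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of the two-step sequential
    decision task. Provides a generative task environment with drifting
    Bernoulli outcome probabilities, a hybrid model-free/model-based
    reinforcement-learning agent (SARSA(lambda) with transition-based
    planning), and an active-inference agent whose expected-free-energy
    action selection trades off preference realisation against
    Beta-Bernoulli information gain, with four surprise/decay belief-update
    variants. Includes per-subject maximum-likelihood fitting by session
    replay with bounded multi-restart optimisation, AIC/BIC model
    comparison, random-effects Bayesian model selection with exceedance,
    protected exceedance and family-level inference, a lagged trial-history
    logistic regression of initial-stage choices, and simulation-based
    parameter and model recovery analyses.
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
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
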