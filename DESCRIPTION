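Package: revlearn
Title: Explicit-Duration Hidden Markov Models of Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Behavioral models of decision making in changing environments,
    built around an explicit-duration hidden Markov model (hidden semi-Markov
    model) agent that carries prior beliefs about the number of trials between
    reward-contingency reversals. Provides negative-binomial duration priors
    and the change-point anticipation profile they induce, approximate
    variational belief updating over states, durations and Beta reward
    beliefs, single- and dual-update Rescorla-Wagner baselines, a softmax
    response model, a probabilistic reversal-learning task simulator,
    synthetic-cohort generation, hierarchical Bayesian parameter estimation
    under a horseshoe prior with mean-field variational inference, posterior
    predictive model evidence, and random-effects Bayesian model comparison
    with exceedance probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
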