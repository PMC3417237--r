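Package: twostepRL
Title: Hybrid Model-Based/Model-Free Reinforcement Learning for the
    Two-Step Markov Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and hierarchical fitting of hybrid
    model-based/model-free reinforcement-learning models for the two-stage
    Markov decision ("two-step") task. Provides a generative task
    environment with Gaussian random-walk reward probabilities, a family of
    choice models (hybrid SARSA/tree-search mixture with softmax and
    perseveration, dual learning rates, separate model-based values, and an
    actor-critic variant), trial-by-trial choice likelihoods with an
    empirical-Bayes two-stage hierarchical estimation procedure, stay-switch
    behavioural analysis with repeated-measures ANOVA, synthetic cohort
    generation for within-subject crossover designs, and parameter-recovery
    tooling.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
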