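Package: beliefbandit
Title: Belief-State and Reinforcement-Learning Models of Two-Armed Bandit
    Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Cognitive modelling toolkit for probabilistic reversal learning
    (two-armed bandit) behaviour and accompanying dopamine photometry.
    Implements a family of trial-by-trial choice models -- Bayesian
    belief-state inference over the hidden rewarded side, hybrid
    belief-state reinforcement learning, and reinforcement-learning
    variants with asymmetric learning rates, counterfactual updates,
    forgetting, Pearce-Hall associability, and meta-learned learning
    rates -- under a common softmax-with-stickiness choice policy.
    Provides maximum-likelihood fitting with multi-start initialization
    and AIC model comparison, a simulate/cross-fit/confusion-matrix model
    identification protocol with parameter recovery, trial-history
    behavioural statistics, fiber-photometry preprocessing (adaptive
    penalized-least-squares baselining, robust isosbestic correction,
    z-scoring, event alignment), and regressions linking model reward
    prediction errors to per-trial dopamine summaries with
    cross-validated log-likelihood model arbitration. A synthetic-data
    module generates task sessions, agent behaviour, event timing and
    dLight-like photometry traces for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    lme4,
    MASS,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
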