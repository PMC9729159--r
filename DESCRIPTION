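Package: prlrel
Title: Reliability Analysis of Probabilistic Reversal Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolbox for two-session probabilistic
    reversal learning task (PRLT) studies. Implements the task's reversal
    schedule and probabilistic feedback, a 24-model space of Q-learning
    models (softmax-temperature and reinforcement-sensitivity families,
    single/double updating, win/loss-specific parameters), subject-level
    parameter estimation by maximum likelihood, MAP with an uninformative
    Gaussian prior, and expectation-maximization MAP with a multivariate
    empirical prior (separate or joint session fitting with value reset),
    integrated-BIC model selection, behavioral metrics (accuracy,
    stay-switch, perseveration, reaction times) as raw proportions and as
    predicted values from mixed-effects models, and a test-retest
    reliability toolbox: ICC(A,1), ICC(1), Pearson correlations with
    confidence intervals, Spearman-Brown correction, model-calculated
    reliabilities from variance components, and variance partitioning.
    Includes simulation experiments probing the recoverability of
    parameters, models, and reliability itself under the different
    estimation regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
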