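Package: toxqsar
Title: Constraint-Aware, Uncertainty-Informed QSAR Modeling of Aquatic Toxicity
Version: 0.1.0
Authors@R: person("toxqsar", "developers", email = "toxqsar@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative structure-activity relationship (QSAR)
    modeling of Tetrahymena pyriformis growth-inhibition toxicity (pIGC50)
    from eight physicochemical descriptors.  Provides monotonicity-constrained
    gradient boosted trees, a mean-field variational Bayesian neural network
    with predictive intervals, genetic-programming symbolic regression,
    cross-validation-weighted ensembling, composite accuracy/reliability
    hyperparameter optimization, and a validation suite covering cluster-aware
    train/test splitting, Y-scrambling, applicability-domain assessment,
    interval calibration metrics, and one-at-a-time perturbation sensitivity
    analysis.  A calibrated synthetic-data generator reproduces the published
    marginal descriptor distributions so the full pipeline is exercisable
    without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
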