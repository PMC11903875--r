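Package: hypnodens
Title: Hypnodensity-Based Quantification of Sleep Intrusions and Instability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous, probabilistic analysis of staged polysomnography.
    From multichannel EEG/EOG recordings paired with 30-second expert
    hypnograms, the package trains personalized gradient-boosted staging
    models whose calibrated outputs are per-epoch sleep-stage probability
    distributions (hypnodensities). Shannon entropy of each hypnodensity
    quantifies stage intrusions and the Kullback-Leibler divergence between
    temporally adjacent same-stage epochs quantifies instability; per-subject
    summaries of these metrics feed minimum-redundancy maximum-relevance
    feature ranking, repeated cross-validated classification of sleeper
    groups, and regression of standard sleep-quality metrics. A synthetic
    PSG cohort generator with controllable intrusion and instability
    structure makes every stage of the pipeline testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    xgboost,
    randomForest,
    pROC,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
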