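Package: fundusCAR
Title: Counterfactual Attribution Ratios for Interpretable Two-Stage
    Retinal Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a two-stage (findings then diseases) classification
    scaffold for retinal fundus images together with the counterfactual
    attribution ratio (CAR), an odds-ratio-style measure of how much each
    abnormal finding contributes to a disease head's prediction.  Provides
    feature-space decomposition along finding-head weight directions,
    instance-level and instance-free attribution ratios, attribution
    activation maps, and interactive score overrides that re-evaluate
    disease probabilities without a new encoder pass.  Also includes
    multi-reader label fusion under a conditional-independence annotator
    model fit by expectation-maximization, severity-aware recoding of
    ordinal annotations, pooled expert odds ratios for comparison against
    model attributions, screening-classifier evaluation utilities
    (AUROC, exact binomial intervals, operating-point selection,
    cosine-distance branch-point analysis), and a synthetic toy-fundus
    generator with known finding-disease structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'model_core.R'
    'encoder.R'
    'car_engine.R'
    'label_fusion.R'
    'expert_stats.R'
    'evaluation.R'
    'synthetic_data.R'
    'io.R'
    'fundusCAR-package.R'
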