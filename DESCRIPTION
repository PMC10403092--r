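Package: ventwarn
Title: Early Warning of Invasive Mechanical Ventilation in the PICU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for early prediction of invasive mechanical
    ventilation (MV) in pediatric intensive care unit (PICU) patients from
    electronic health record event streams. Provides a synthetic PICU cohort
    generator with planted physiologic and medication-sequence signal,
    inclusion/exclusion cohort filtering, 5-minute last-observation-carried-
    forward feature grids with age-normalized physiologic z-scores,
    medication-history sentence representation learning (GloVe embeddings
    feeding a 1-D convolutional feature extractor), gradient-boosted-tree and
    L1-logistic risk-score models with max-F1 threshold selection, early
    prediction point / early warning time computation with dual-threshold and
    waiting-period variants, Pediatric Early Warning Score comparators, and
    spectral clustering of post-alert risk-score trajectories into risk groups
    with bootstrap Jaccard stability assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    xgboost,
    glmnet,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
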