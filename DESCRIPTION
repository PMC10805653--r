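Package: densomics
Title: Dense Multi-Omics Microsampling Time-Course Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for dense, irregularly sampled multi-omics
    microsampling studies paired with wearable-sensor streams. Implements
    lagged cross-correlation between asynchronous time series with a
    Gaussian-fit quality score, AUC-based metabolic response scoring of a
    standardized meal challenge, day-wise LOESS smoothing with consistency
    scoring and Lomb-Scargle circadian rhythmicity testing, fuzzy c-means
    temporal clustering with correlation-network community modules,
    storage-stability regression with partial R-squared and LMG variable
    importance, and wearable-feature random-forest prediction of blood
    analytes. Ships a seeded synthetic-data generator with known ground
    truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    e1071,
    igraph,
    randomForest,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core_io.R'
    'dense_profiling.R'
    'laggedcor.R'
    'metabolic_scores.R'
    'shake_response.R'
    'stability_qc.R'
    'synthetic_data.R'
    'wearable_prediction.R'
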