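Package: ctcsPR
Title: Predicting Coronary Positive Remodeling from Calcium-Scoring CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to predict coronary positive remodeling (PR) from
    non-contrast calcium-scoring CT. Implements per-vessel and total
    Agatston scoring with derived features (log scores, diffusivity
    index, high-CAC flag), epicardial fat-omics feature extraction
    (morphological, intensity, and spatial slab/ribbon Hounsfield-unit
    histogram features), remodeling-index computation and PR labeling,
    an elastic-net feature-selection plus gradient-boosted
    classification pipeline evaluated by repeated stratified
    cross-validation with McNemar/DeLong model comparisons, and
    Kaplan-Meier/Cox survival analysis of predicted PR against major
    adverse cardiovascular events. A synthetic-data module provides CT
    phantoms and a cohort simulator so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    xgboost,
    randomForest,
    e1071,
    pROC,
    survival,
    RNifti,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
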