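Package: radsel
Title: Two-Step Ensemble Radiomic Feature Selection for Binary Molecular
    Marker Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds binary predictors of breast-cancer molecular markers
    (ER, PR, HER2, Ki67) from high-dimensional radiomic feature tables.
    Implements a two-step ensemble feature-selection pipeline: complete
    ranker filters (chi-squared, Fisher score, Gini index, ReliefF) scored
    per cross-validation fold and aggregated across folds by minimal rank
    (minpos) and its multiplicity (numpos), followed by a fine-tuning step
    (LASSO recursive feature elimination, mutual information, CFS), with
    SMOTE class balancing inside every training split and leave-one-out
    model selection by F1-score. Also provides IBSI-style radiomic feature
    extraction from 3D volumes and masks (shape, first-order, GLCM, GLRLM,
    GLSZM, NGTDM, GLDM families; single-level wavelet and
    Laplacian-of-Gaussian filtered channels) and a synthetic-data module
    generating feature tables with planted informative features and dynamic
    lesion phantoms for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    glmnet,
    igraph,
    nnet,
    randomForest,
    rpart,
    RNifti,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
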