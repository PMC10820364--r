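Package: aopqsar
Title: Multi-Encoder QSAR Modelling of Adverse-Outcome-Pathway Cardiotoxicity Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary QSAR classifiers for adverse-outcome-pathway (AOP)
    cardiotoxicity endpoints from raw SMILES and assay hit-call matrices.
    Covers structure curation (canonicalization, salt stripping, duplicate
    merging), hit-call aggregation into per-endpoint activity labels, five
    chemical representations (molecular descriptors, circular and MACCS
    fingerprints, molecular graphs, tokenized SMILES, latent codes),
    SMILES-enumeration data augmentation, SMOTE-family oversampling,
    applicability-domain consensus (bounding box, PCA box, leverage, centroid
    distance, variable-k nearest neighbours), a model battery from logistic
    regression to message-passing and five-branch multimodal neural networks,
    stratified evaluation with six confusion-matrix metrics, permutation
    importance and Shapley attributions, plus a synthetic benchmark generator
    with planted toxicophore ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
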