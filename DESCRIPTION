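Package: polyen
Title: Polynomial Elastic-Net Aging Clocks from Single-Cell Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts donor chronological age from single-cell RNA-seq data.
    Per-donor, per-cell-type expression means and variances are expanded into
    first- and second-degree polynomial features and fed to an elastic-net
    regressor with sequential model-based hyperparameter tuning. Includes
    leave-one-out and cross-dataset evaluation protocols, mean-only linear
    baselines, exact linear SHAP feature attribution with permutation-based
    empirical gene p-values, pre-ranked GSEA export, and a synthetic
    multi-donor cohort simulator with controllable age signal in expression
    means and cell-to-cell variances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), glmnet, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
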