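Package: habitomics
Title: Habitat Radiomics, 2.5D Multi-Instance Learning and Nomogram
    Modelling for CT Tumor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete, testable pipeline for predicting binary clinical
    endpoints (such as post-treatment lymph-node metastasis) from
    contrast-enhanced CT: intensity clipping, isotropic resampling and
    fixed-bin-width discretization; K-means delineation of intratumoral
    habitats from voxel-wise local first-order features; a 1834-feature
    handcrafted radiomic bank (shape, first-order and five texture-matrix
    families over a 20-image filter bank); an ICC / t-test / correlation /
    LASSO feature-selection cascade; 2.5D five-slice stacks fused into
    patient-level multi-instance features via predict-likelihood histograms
    and bag-of-words TF-IDF; clinicoradiological logistic signatures and a
    fusion nomogram; and an evaluation suite with DeLong AUC inference,
    bootstrap calibration, Hosmer-Lemeshow and decision-curve analysis.
    A synthetic-cohort generator with planted subregion structure makes
    every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    glmnet,
    ranger,
    e1071,
    xgboost,
    nnet,
    jsonlite,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
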