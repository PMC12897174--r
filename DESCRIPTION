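Package: hafnet
Title: Multimodal Fusion of Hyperspectral Pathology and MRI Radiomics for Glioma Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies hyperspectral microscopy patches of adult diffuse gliomas
    into the six WHO-2021 type/grade classes (A2, A3, A4, O2, O3, G4) by fusing
    mutual-information-selected spectral channels with MRI-derived radiomic
    feature vectors. Provides white/dark reflectance calibration and ENVI cube
    I/O, non-overlapping tumor-patch extraction, histogram mutual-information
    wavelength ranking, a 5650-feature radiomic schema contract with z-score
    normalization, a 3D convolutional attention-fusion network trained with
    weighted cross-entropy under stratified cross-validation, one-vs-rest
    macro-AUC / macro-F1 / confusion-matrix evaluation with paired fold-level
    t-tests, and a synthetic-data generator emulating calibrated reflectance
    cubes with class-specific absorption signatures paired with complementary
    radiomic vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cli.R'
    'dataset-io.R'
    'envi.R'
    'evaluation.R'
    'experiments.R'
    'hafnet-model.R'
    'hafnet-package.R'
    'hsi-io.R'
    'nn-layers.R'
    'radiomics.R'
    'synthetic.R'
    'training.R'
    'wavelength.R'
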