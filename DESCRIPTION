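Package: strokefate
Title: Tissue Outcome Prediction from 4D CT Perfusion Imaging
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end framework for voxelwise prediction of follow-up
    infarct lesions in acute ischemic stroke from baseline 4D CT perfusion
    (CTP) imaging. Covers the full chain from raw spatiotemporal series to
    predicted lesion masks: baseline correction and temporal resampling,
    brain and hemisphere masking, block-circulant SVD deconvolution with an
    arterial input function, perfusion parameter mapping (CBF, CBV, MTT,
    Tmax), model-ready tensor preparation, and five tissue outcome
    predictors (optimal Tmax thresholding with leave-one-out threshold
    selection, a voxelwise random decision forest, and modular UNet models
    with learned temporal features from residual or concentration-time
    curves) evaluated under patient-level fivefold cross-validation. A
    synthetic digital CTP head phantom with known hemodynamic ground truth
    makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    Rcpp,
    RNifti,
    EBImage,
    ranger,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
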