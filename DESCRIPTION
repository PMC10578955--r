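Package: qusradiomics
Title: Quantitative Ultrasound Radiomics for Treatment-Response Modelling
Version: 0.1.0
Authors@R: person("QUS", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantitative ultrasound (QUS) radiomics:
    simulation of radiofrequency (RF) speckle frames and calibration
    phantoms with known ground truth, reference-phantom power-spectrum
    normalisation, spectral-line parameters (mid-band fit, spectral slope,
    spectral intercept), backscatter form-factor fitting of effective
    scatterer diameter and acoustic concentration under Gaussian and
    fluid-sphere (Anderson) models, sliding-window parametric maps,
    gray-level texture matrices (GLCM, GLRLM, GLSZM, GLDM) with a
    68-feature catalogue, higher-order texture-of-texture maps, and a
    leakage-safe machine-learning harness (SMOTE, z-scoring, sequential
    forward selection by F1, SVM and k-NN, leave-one-out cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
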