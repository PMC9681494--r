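Package: drdetect
Title: Diabetic Retinopathy Detection from Fundus Images by Fusing Deep and
    Clinical Lesion Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for binary diabetic-retinopathy (DR)
    detection from color fundus photographs. Retinal lesions
    (microaneurysms, exudates, hemorrhages) are segmented with patch-based
    U-Net models trained under k-fold cross-validation with a binary focal
    loss, patch predictions are merged into full-resolution probability
    maps, and lesion counts are extracted by edge/contour analysis of the
    binarized maps. The three lesion counts are fused by flat concatenation
    with flattened deep features from topless VGG-16 or ResNet-50 backbones
    and classified with gradient-boosted trees. A synthetic fundus
    generator with paired ground-truth masks makes every stage testable
    without external image datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
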