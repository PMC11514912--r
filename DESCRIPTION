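Package: blastometry
Title: 3D Blastocyst Morphometry and Non-Invasive Euploidy Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative 3D morphology measurement of human blastocysts from
    rotated multi-view microscopy images: sphere construction from a mid-plane
    image, feature-based estimation of inter-view rotations, projection and
    stitching of views onto a spherical surface map, and measurement of five
    morphological parameters (diameter, trophectoderm cell number, density and
    size variance, and inner cell mass area). Includes a synthetic blastocyst
    renderer with known ground truth, association statistics (univariate and
    forward stepwise logistic regression, two-sample tests, correlations), an
    interpretable decision-rule classifier for euploidy, and a multi-model
    benchmark harness with exact binomial confidence intervals, DeLong and
    McNemar tests, and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    rpart,
    xgboost,
    randomForest,
    e1071,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
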