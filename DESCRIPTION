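Package: kneeage
Title: Automated Age Estimation from 3D Knee MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline for forensic age estimation from 3D
    knee magnetic resonance volumes. Raw volumes are standardized (bias-field
    correction, in-plane resampling, template-matching localization, fixed
    130 mm volume-of-interest extraction), age-relevant bone structures are
    extracted with an encoder-decoder segmentation network, volumes are
    reduced to twelve informative slices, per-slice ages are regressed with a
    compact convolutional network, and subject-level age estimates plus a
    minor/adult classification are produced by tree-ensemble aggregation of
    the slice predictions. Includes a synthetic knee-phantom generator with a
    recoverable growth-plate age signal, the repeated stratified five-fold
    cross-validation evaluation protocol, and statistical-reference baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    ranger,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    xgboost,
    class
Config/testthat/edition: 3
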