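Package: spadspec
Title: Hyperspectral Band Selection and SPAD Inversion Mapping for Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating leaf chlorophyll (SPAD) from visible/near-infrared
    hyperspectral images: reflectance calibration of raw hypercubes against white and
    dark references, extraction of region-of-interest mean spectra, characteristic
    wavelength selection by Spearman correlation screening, stability competitive
    adaptive reweighted sampling (sCARS) and iteratively retaining informative
    variables (IRIV), cross-validated regression modelling (PLSR, XGBoost, random
    forest, gradient-boosted trees), and pixel-wise SPAD inversion maps with
    per-leaf statistics. Includes a synthetic-data generator producing
    vegetation-like spectra and full hypercubes with known ground truth, and a
    pipeline driver that runs the whole workflow reproducibly from a single
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    xgboost,
    randomForest,
    rpart,
    yaml,
    jsonlite,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
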