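Package: yieldnet
Title: Multi-Crop Yield Prediction from Remote-Sensing Pixel Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simultaneous county-level corn and soybean yield prediction from
    multispectral satellite composite time series. Raw imagery is reduced to
    per-band pixel-value histogram tensors under a permutation-invariance
    assumption, and a dual-head convolutional network with a shared backbone
    maps histograms to both crop yields at once, trained with a normalized
    max-loss that puts the two crops on a common scale. Includes classical and
    neural baselines, an in-season progressive forecasting protocol with
    year-held-out splits, an ablation over single-head variants, and a
    synthetic data generator with known ground truth so the full pipeline is
    testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    Rcpp,
    glmnet,
    ranger,
    rpart,
    tiff,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
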