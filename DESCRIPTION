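Package: wheatlfanet
Title: Lightweight Real-Time Detection and Counting of Wheat Heads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A from-scratch implementation of WheatLFANet, a lightweight
    single-stage global-regression detector for counting wheat heads in field
    images. Provides the encoder/decoder network (cross-stage partial layers,
    a simplified CSP spatial-pyramid-pooling-fast neck, conv/BN fusion),
    anchor assignment and the composite training loss with missing-label
    attenuation, decoding and non-maximum suppression, detection (precision,
    recall, average precision, F1-confidence area) and counting (MAE, RMSE,
    MAPE, R2) evaluation, GWHD-style annotation I/O, a synthetic wheat-canopy
    scene generator for desk-scale training, and an SGD training loop with a
    cosine learning-rate schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    optparse
Config/testthat/edition: 3
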