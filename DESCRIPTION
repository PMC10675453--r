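Package: counet
Title: Cardiac Output Estimation from PPG and Arterial Pressure Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates cardiac output (CO) from paired photoplethysmography
    (PPG) and invasive arterial pressure (ART) waveforms with a dual-channel
    one-dimensional U-Net regression model augmented with bidirectional LSTM
    layers. Provides a physiologically structured waveform simulator with a
    known ground-truth waveform-to-CO relationship and targeted artifact
    injection, Butterworth band-pass preprocessing and 2048-point
    segmentation, a seven-rule segment quality screen, network training and
    prediction on CPU, and a method-comparison statistics suite (bias, limits
    of agreement, RMSE, RMSNE, percentage error, Pearson correlation,
    Bland-Altman data, identity-line least-squares fit).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
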