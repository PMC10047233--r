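Package: ceustic
Title: Time-Intensity Curve Extraction and Lesion Classification for
    Contrast-Enhanced Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An automated pipeline for contrast-enhanced ultrasound (CEUS)
    liver studies. Reads two-panel ultrasound video (B-mode plus contrast
    mode with a vertical colorbar), crops the named regions, derives a
    colorbar lookup table, extracts lesion and surrounding-parenchyma
    time-intensity curves at 1 Hz with a probe-lift validity rule and
    Savitzky-Golay smoothing, and summarises each curve by its maximum
    intensity, time to peak, area under the curve and mean transit time.
    A small feed-forward network trained with focal cross-entropy
    classifies lesions into five diagnostic classes from the curve
    parameters and clinical covariates; multiclass evaluation (categorical
    accuracy, micro/macro F1, Matthews correlation) is included, together
    with a synthetic phantom generator and a compact trainable U-Net so
    every stage can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    signal,
    pracma,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
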