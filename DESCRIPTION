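Package: ldasg
Title: Low-Distortion Adaptive Savitzky-Golay Filtering for ECG Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Denoising of single-channel electrocardiogram (ECG) recordings
    with a Savitzky-Golay filter whose polynomial order is selected per
    sample from a discrete-curvature estimate of the signal.  Local
    curvature is measured by growing digital straight segments (DSS) on
    either side of each sample and combining their lengths and slope
    angles; uniform quantisation maps curvature to a bank of precomputed
    Savitzky-Golay convolution weights, so flat regions receive strong
    smoothing while sharp deflections such as QRS complexes keep a high
    order and low distortion.  Includes a synthetic ECG generator, exact-SNR
    contamination with white, pink (1/f) and muscle-artifact noise, the
    standard SNR-improvement / MSE / PRD evaluation metrics, delimited-text
    and WFDB signal input, and a benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
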