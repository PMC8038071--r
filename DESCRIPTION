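Package: contrp
Title: Continuous Recurrence Plots and Multimodal CNNs for Driving-Stress
    Detection from Short-Term Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects driver stress from short-term (10-30 s) foot/hand
    galvanic skin response (FGSR, HGSR) and heart rate (HR) signals.
    Raw multi-channel recordings are resampled to 16 Hz, median filtered,
    z-normalized and segmented into 50%-overlap windows labeled from a
    marker channel delimiting rest, highway and city driving periods.
    Each window is converted into a continuous recurrence plot (the
    unthresholded pairwise Euclidean distance matrix of its time-delay
    embedding), and the (FGSR, HGSR, HR) plot triple is classified as
    stressed versus relaxed by a three-branch convolutional neural
    network trained with SGD, evaluated under leave-one-recording-out
    cross-validation.  A synthetic-recording generator emulating the
    rest/highway/city driving protocol makes the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
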