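Package: hfokit
Title: Modular Detection and Classification of High-Frequency Oscillations in EEG
Version: 0.1.0
Authors@R: person("HFO", "Toolkit Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A scriptable toolkit for detecting and classifying
    high-frequency oscillations (HFOs: ripples, 80-250 Hz, and fast
    ripples, 250-500 Hz) in multichannel EEG. Provides EDF+ input/output
    and recording segmentation, a synthetic EEG generator with exact
    ground truth, windowed-sinc FIR and empirical-mode-decomposition
    preprocessing, RMS and Hilbert-envelope event detectors, time-domain
    and spectral feature extraction, a Stockwell-transform spectral
    peak/trough classifier, an RBF-kernel support vector machine with
    ANOVA-ranked wrapper feature-subset selection and grid parameter
    optimization, event-overlap validation metrics, HFO activity
    reports, and an XML-configurable process pipeline with a plugin
    registry and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
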