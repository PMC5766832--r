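Package: whiskerlfp
Title: Behavioral and Electrophysiological Analysis of Whisker Detection Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed go/no-go whisker detection
    experiments with multi-area local field potential (LFP) and single-unit
    recordings. Implements signal-detection performance measures (d-prime with
    loglinear correction, trained-session selection), sensory-evoked potential
    (SEP) extraction with artifact blanking, zero-phase band-pass filtering,
    baseline correction and first-peak measurement, sliding-window ROC
    "stimulus probability" decoding with label-shuffle chance bands, PSTH and
    bootstrap firing-rate modulation tests for regular- and fast-spiking units,
    optogenetic and pharmacological inactivation statistics, and a
    nonparametric toolkit including the Dunn-Holland-Wolfe joint-rank multiple
    comparison procedure. A synthetic cohort generator emulates the trial
    structure, learning curves, area-specific evoked kernels and spiking
    statistics of such experiments so every analysis is testable without
    recorded data. Sessions round-trip through an HDF5 container with CSV
    trial-table mirrors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rhdf5,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
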