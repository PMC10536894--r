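Package: eegfusion
Title: Multi-Branch Convolutional Networks for Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-subject motor-imagery electroencephalography (EEG)
    decoding with multi-branch convolutional neural networks. Provides a
    synthetic EEG generator with class-dependent event-related
    desynchronization, EDF+ reading and writing, zero-phase Butterworth
    band-pass and notch filtering, epoching and non-overlapping windowing,
    a five-branch depthwise/separable convolutional fusion classifier
    trained with Adam and best-validation checkpointing, and one-vs-rest
    precision/recall/F1 evaluation. The network, filters and file formats
    are implemented natively so the full pipeline runs on synthetic data
    with no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
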