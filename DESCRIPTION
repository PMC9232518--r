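Package: bsfc
Title: Label-Free Detection of Circulating Tumor Cell Clusters in
    Backscatter Flow Cytometry Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Signal-processing and classification pipeline for detecting
    circulating tumor cell clusters (CTCCs) in whole blood from confocal
    backscatter flow cytometry time traces. Provides a seeded synthetic
    trace simulator with ground-truth annotation, zero-phase Butterworth
    band-pass filtering, daily reflectance-standard power normalization,
    3-sigma threshold peak detection with full-width-at-half-maximum
    gating based on slit-transit flow physics, green-fluorescence
    ground-truth labeling, windowed feature extraction with four segment
    normalization methods, a Gentle AdaBoost tree ensemble trained on
    class-balanced resamples, sequential cascade evaluation, and
    confusion-matrix performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
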