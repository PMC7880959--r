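Package: gazevents
Title: Adaptive Velocity-Based Classification of Eye-Movement Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies dense monocular gaze coordinate recordings into
    fixation, saccade, post-saccadic oscillation, and smooth-pursuit events
    using an adaptive, robust velocity-thresholding approach.  Velocity
    thresholds are estimated iteratively from median and median-absolute-
    deviation statistics of sub-threshold velocities, recordings are chunked
    at major saccades so thresholds adapt to local noise levels, and the
    remaining signal is segmented into pursuit and fixation periods after
    low-pass filtering.  Ships sample-level agreement metrics (Cohen's kappa,
    Jaccard index, misclassification proportion, duration-statistics RMSD),
    BIDS-style event table output, a diagnostic visualization, and a
    deterministic synthetic gaze generator with sample-level ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
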