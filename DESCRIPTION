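Package: gazemodes
Title: Ambient-to-Focal Mode Switching in Free-Viewing Eye Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of free-viewing gaze recordings around visual objects:
    saccade and fixation detection from raw gaze traces via Savitzky-Golay
    kinematics, object-based classification of fixations and saccades,
    descriptive dynamics (per-bin and per-order type ratios, fixated-object
    counts), and a two-mode Markov model of saccade-sequence generation with
    a one-way ambient-to-focal switch. Includes exact expected type-ratio
    curves, exhaustive grid-search fitting of the model by a goodness-of-fit
    measure, AIC comparison of switch versus no-switch variants, single-trial
    posterior inference of the switch time, and a synthetic-data generator
    that renders model-driven gaze traces so the whole pipeline is testable
    without recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
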