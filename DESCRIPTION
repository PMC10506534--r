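Package: saccadescope
Title: Saccade Detection and Saccade-Locked Calcium Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing saccadic eye movements and their neural
    correlates in head-fixed mouse calcium-imaging experiments. Detects
    saccades from angular eye-position traces with a two-threshold speed
    rule and noise-based validation, summarises saccadic behaviour
    (intersaccade intervals, direction and magnitude asymmetries,
    per-stimulus saccade frequency), classifies neurons as
    saccade-responsive (enhanced, suppressed, direction-selective) against
    a session-weighted bootstrap null of event-triggered dF/F changes, and
    compares drifting-grating and natural-scene tuning metrics (DSI, OSI,
    lifetime sparseness) between neuronal populations. Includes a
    synthetic-data generator producing gaze traces, stimulus epochs and
    dF/F matrices with known ground truth, plus an end-to-end pipeline
    with plain-text file formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
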