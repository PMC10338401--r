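Package: surgevents
Title: Console Event Detection, Hand-Path Kinematics and Annotation
    Tooling for Robot-Assisted Surgery Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw recordings of a surgical-robot console ocular feed
    into machine-learning-ready data. Detects discrete console events
    (cut, coagulation, clutch, third-arm swap, camera movement) from the
    on-screen indicator panels by normalized-correlation template matching
    inside configured regions of interest; computes surgeon hand-path
    metrics (path length in pixels) from landmark streams with pluggable
    detectors; parses behavioral-observation TSV annotations into paired
    START/STOP intervals and aggregates label counts; and summarizes event
    totals and per-minute rates by procedure and experience group. A
    bundled synthetic console-video simulator renders scripted event
    timelines with exact ground truth, so the whole pipeline is testable
    without proprietary robot imagery. Videos are handled as lossless
    PNG frame-sequence directories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
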