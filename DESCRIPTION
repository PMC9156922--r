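Package: rspgait
Title: Running Gait Biomechanics and Between-Leg Asymmetry from Vertical
    Ground Reaction Forces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline from raw treadmill vertical ground-reaction-force
    signals to per-leg running biomechanics and between-leg asymmetry for
    athletes running with running-specific prostheses. Conditions force and
    marker signals (drift correction, zero-phase Butterworth filtering),
    detects ground-contact events with a 20 N threshold, labels stances by
    leg, derives per-step contact length, stance-average vertical force and
    step frequency, computes between-leg symmetry indices, and fits linear
    mixed-effects models for the effects of prosthesis model, stiffness
    category and height across running speeds. Includes a synthetic
    ground-reaction-force and trial-table generator with known ground truth
    so every stage is verifiable without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
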