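Package: hypoval
Title: Event-Based Forward Validation of Continuous Hypotension Prediction Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating a continuous 0-100 hypotension prediction
    index against invasive mean arterial pressure (MAP) time series on a
    20-second grid. Implements event-based forward validation: detection of
    hypotensive events (MAP < 65 mmHg sustained at least one minute) and
    index alerts (threshold exceedance sustained at least one minute),
    labeling of 20-minute prediction windows as true/false
    positives/negatives, threshold sweeps with sensitivity, specificity,
    predictive values (Wilson score intervals) and time-to-event summaries,
    ROC curves with trapezoidal AUROC, and the time-weighted average depth
    of hypotension. Includes artifact censoring for arterial-line
    recordings and a seeded synthetic cohort generator with known ground
    truth for pipeline testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
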