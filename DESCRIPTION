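Package: ehrqa
Title: Score-Based Quality Assessment for Longitudinal EHR Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated plausibility scoring for repeated continuous measurements
    in electronic health record (EHR) data. Each observation receives a
    longitudinal plausibility score: the two-sided normal p-value of its
    standardized absolute deviation from an exponentially weighted moving
    average (EWMA) over the subject's own measurement history, with weights
    decaying in the time gap. An atemporal population-thresholding score is
    provided for comparison, together with record-level eligibility filters,
    subject-level aggregation, a body-mass-index classification use case, a
    labeled synthetic-cohort generator with injected errors, an evaluation
    harness (false-positive rate, power, predictive values, ROC, parameter
    sweeps), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pROC
Config/testthat/edition: 3
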