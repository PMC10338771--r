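Package: ptvmargins
Title: PTV Margin Estimation for Robotically Tracked Moving Tumors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating clinical-to-planning target volume (CTV to
    PTV) margins for respiratory-tracked tumors treated with robotic
    stereotactic body radiotherapy. Implements the van Herk margin recipes,
    their five-component extension for robotic tracking systems, and a
    covariance-augmented variant that propagates the correlation between
    correlation-model and prediction errors into the random-error term.
    Includes readers and writers for a documented per-fraction tracking-log
    CSV schema, systematic/random error decomposition, Pearson and distance
    correlation estimation between error streams, adaptive first-fraction
    margin workflows, covariance envelopes, cohort-level F-test method
    comparison, and a hierarchical synthetic-cohort simulator so the whole
    pipeline is testable without clinical log files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
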