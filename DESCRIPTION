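Package: ascvdcea
Title: Markov Cohort Cost-Effectiveness Model for LDL-C-Lowering Add-On
    Therapy in ASCVD
Version: 0.1.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A six-state annual-cycle Markov cohort model evaluating the
    cost-effectiveness of adding the siRNA LDL-C-lowering agent inclisiran
    to statin therapy for Chinese patients with atherosclerotic
    cardiovascular disease (ASCVD). Implements baseline event-rate
    calibration (ethnicity/age/LDL-C adjustment, composite-rate
    disaggregation, rate-probability conversion), treatment-effect mapping
    through Cholesterol Treatment Trialists' Collaboration rate ratios,
    life-table competing mortality, half-cycle-corrected discounted cost
    and QALY accumulation, ICER/NMB decision rules, tornado one-way
    sensitivity analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, time-horizon scenario sweeps,
    and a synthetic Gompertz-Makeham life-table generator so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
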