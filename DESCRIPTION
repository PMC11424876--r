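Package: fihpk
Title: Non-Compartmental Analysis, Dose Proportionality and Whole-Body
    PBPK Simulation for First-in-Human Single-Ascending-Dose Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pharmacokinetic analysis of first-in-human
    single-ascending-dose studies: standard non-compartmental analysis
    (Cmax, Tmax, AUC by linear-up/log-down trapezoid, terminal slope by
    best-fit log-linear regression, half-life and apparent clearance),
    power-model dose-proportionality assessment with the Smith
    acceptance-range criterion, a 14-tissue perfusion-limited whole-body
    physiologically based pharmacokinetic (PBPK) simulator with
    single-dose calibration and dose scanning, fold-error model
    validation with 2-fold/3-fold banding, and a synthetic-cohort
    generator with log-normal inter-subject variability so every stage
    can be exercised without clinical data.  Ships the group-level
    summaries, drug-specific model inputs and predicted/observed
    exposure table from the NH130 (a selective serotonin 5-HT2A inverse
    agonist) phase I dose-escalation program as packaged reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
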