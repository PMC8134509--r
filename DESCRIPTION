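Package: symptomPGM
Title: Probabilistic Graphical Models of Antidepressant Symptom Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal 17-item Hamilton Depression
    Rating Scale (HDRS-17) cohorts measured at baseline, week 4 and week 8 of
    antidepressant treatment. Stratifies patients by total depression severity
    at each timepoint with BIC-selected Gaussian mixtures, derives most-likely
    severity trajectories with a forward-transition hidden Markov model, mines
    depressive symptoms whose 4-week change is prognostic of the 8-week
    outcome (remission, response or nonresponse), and derives and evaluates
    rule-based prognoses (coverage, accuracy, odds ratios and significance
    against a null information rate), with frozen-rule replication on
    independent cohorts. Includes a synthetic-cohort simulator with a planted
    prognostic-symptom signal so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
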