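Package: mcitriage
Title: Evaluation of In-Hospital Mass-Casualty Triage Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes mass-casualty triage algorithms (mSTaRT, PRIOR, the
    Berlin algorithm, the Manchester Triage System MCI module, the Emergency
    Severity Index, and the Jordanian-German project algorithms JorD and
    PETRA) as declarative decision trees, runs them over coded patient
    vignettes with step accounting, forms an expert-consensus reference
    standard by median rating, and evaluates each algorithm's diagnostic
    accuracy (sensitivity, specificity, predictive values, Youden index),
    over-/under-triage profile, step cost, and casemix-weighted triage-time
    workload. A seeded synthetic-vignette and expert-panel simulator makes
    the whole pipeline exercisable without access to unpublished study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
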