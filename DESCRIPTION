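Package: besplit
Title: Gini-Index Split Points for Adverse Events in Pooled Bioequivalence Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled bioequivalence (BE) study databases:
    per-study Gini-impurity split-point estimation on subject-mean Cmax and AUC
    against binary adverse-event class labels, pooled above/below-split
    adverse-event probabilities overall and per ATC level-1 drug subgroup,
    descriptive adverse-event frequency tables, unit harmonization and
    log-scale distributional checks, and a seeded synthetic BE-data generator
    for parameter-recovery and calibration experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    readr,
    dplyr,
    tibble,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
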