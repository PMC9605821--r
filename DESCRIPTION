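Package: hemod
Title: Rule-Based Detection of Hematologic Organ Dysfunction in Pediatric Intensive Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sepsis-associated hematologic organ dysfunction on sparse
    laboratory time series from pediatric intensive care stays using the
    International Pediatric Sepsis Consensus Conference criteria (platelet
    count below 80,000/mm3, a 50 percent platelet decline from the admission
    baseline in chronic hematology/oncology patients, or an international
    normalized ratio above 2), with configurable diagnosis-based gating and
    suppression of platelet alarms around extracorporeal membrane oxygenation
    episodes. Provides a block-based diagnostic-accuracy evaluation against a
    clinician reference standard with cluster-robust Wald confidence
    intervals for sensitivity and specificity, a reproducible synthetic
    cohort simulator with injected ground-truth dysfunction episodes, flat
    file readers and writers for LOINC-coded observations and ICD-10-GM
    diagnoses, and a command-line pipeline tying simulation, detection,
    evaluation and reporting together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
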