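Package: prmstrat
Title: Biomarker Panel Selection and Recurrence Risk Stratification from
    Targeted Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline that turns transition-level parallel
    reaction monitoring (PRM) quantities into a spike-in-normalized protein
    matrix, screens all small marker combinations with paired bootstrapped
    cross-validated random forests, builds the set of statistically
    equivalent top panels and their feature prevalences, and evaluates the
    resulting risk score with ROC, DeLong, Kaplan-Meier, and
    likelihood-ratio statistics. Includes a synthetic serum-cohort
    generator with planted informative proteins, per-sample batch factors
    removable by a spike-in reference, and abundance-dependent missingness,
    so that every stage is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
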