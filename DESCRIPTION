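Package: sersev
Title: Single-Vesicle SERS Fingerprint Analysis for Liquid-Biopsy Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing surface-enhanced Raman (SERS) spectra of
    single small extracellular vesicles (sEVs). Implements the full
    chemometric chain used in SERS liquid-biopsy studies: asymmetric
    least-squares fluorescence baseline removal, Savitzky-Golay smoothing and
    min-max normalisation; Euclidean/correlation fingerprint comparison with
    hierarchical subtyping; correction of label noise arising from vesicle
    sub-populations shared between patient and control donors (relabeling);
    RBF-SVM classification with stratified 80/20 repeated cross-validation
    and shrinkage LDA projections; donor-level leave-a-pair-of-samples-out
    ROC/AUC validation; tracking of patient-unique vesicle types across
    tissue, blood and saliva; band-intensity heat maps from fine Raman map
    scans; and a fully seeded synthetic-cohort generator with exported ground
    truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
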