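Package: classaudit
Title: Auditing Clinical Variant Classification Accuracy Over Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to audit the accuracy of clinical variant-classification
    databases over time using a reference cohort. Harmonizes dated
    classification snapshots in ClinVar-style (archive 1.0 numeric codes,
    archive 2.0 string labels) and HGMD-style dialects onto fixed category
    ladders, normalizes variant identities, applies the 2015 and 2018 BA1
    stand-alone-benign allele-frequency filters, scans phased cohort
    genotypes for database-implied pathogenic genotypes (homozygous,
    hemizygous, compound heterozygous), quantifies false-positive rates and
    ancestry skew with exact conditional contingency-table inference, and
    measures variant recategorization with variant-months normalization.
    Includes a synthetic-data generator with a machine-readable ground-truth
    ledger so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
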