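Package: monomethir
Title: Monocyte DNA Methylome Analysis of Insulin Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential methylation analysis of Illumina 450K beta values
    for insulin-resistance phenotyping in monocytes: permutation
    empirical-Bayes moderated-t testing with an absolute effect-size filter,
    SNP-pattern and confounder probe exclusion, reference-based cell-identity
    scoring, hematopoietic stem cell methylation-maintenance classification,
    logistic-regression biomarker derivation with beta-value cutoffs, cohort
    statistics (HOMA-IR stratification, exact Mann-Whitney, genomic-context
    enrichment, Manhattan clustering, power analysis), and a synthetic cohort
    generator with a ground-truth ledger so the full pipeline is testable
    offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
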