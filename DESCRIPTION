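Package: rarecnv
Title: Rare Copy-Number Variant Burden Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for rare copy-number variant (CNV) burden
    association studies on SNP-array callsets: dual-caller consensus calling
    with gain/loss conflict exclusion and gap annealing of fragmented calls,
    sample- and CNV-level quality control (Q3+3IQR outlier rules, aneuploidy,
    centromere/telomere/segmental-duplication and frequency filters), burden
    encoding at four genomic scales (genome-wide span, neurodevelopmental
    region carrier status, gene indicators, gene-set counts), per-cohort
    linear/logistic/ordinal regression with array-quality covariates,
    heteroskedasticity-robust sensitivity analyses, polygenic-score joint
    models, and fixed-effects inverse-variance-weighted meta-analysis with
    Benjamini-Hochberg false-discovery control within test families. Includes
    a synthetic-data generator with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    MASS,
    sandwich,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
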