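Package: metsig
Title: Metastatic Expression Signatures for Matched Primary/Metastasis
    Ovarian Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for matched primary and omental-metastasis
    ovarian tumor cohorts: paired differential expression with
    Benjamini-Hochberg false discovery control, derivation and scoring of a
    median-dichotomized vote-based prognostic gene signature, Kaplan-Meier and
    log-rank survival evaluation with a random gene-set empirical null,
    array-CGH outlier smoothing, circular binary segmentation and gene-level
    copy-number scoring with recurrent metastasis-specific aberration calls,
    and paired staining (Ki-67/TUNEL) statistics. Includes a synthetic-data
    generator that emulates the statistical structure of such cohorts so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    limma,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
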