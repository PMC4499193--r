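Package: paneltriage
Title: Panel-Based Clinical Variant Triage with a Five-Stage Filtration
    Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for symptom-based gene-panel diagnostics of Mendelian
    disease: a versioned panel registry with clinical-feature routing and
    spike-in updates, a five-stage variant filtration cascade (functional
    class, public allele frequency, in-house cohort occurrence, call
    quality, zygosity) with per-stage funnel reporting, an accumulating
    in-house variant occurrence database with common-pathogenic-variant
    flagging, microarray CNV classification by log2-ratio, probe-count
    and size thresholds with de novo pathogenicity calls, analytical and
    clinical sensitivity/specificity accounting, and a seeded synthetic
    cohort generator for end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
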