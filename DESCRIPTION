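Package: chromstrat
Title: Unsupervised Chromatin-Accessibility Stratification of Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies tumors by chromatin accessibility from ATAC-seq peak
    data and runs the downstream regulatory analyses: union peak set
    construction, per-tumor rank normalization, UMAP embedding and group
    assignment, group-vs-rest log2 fold-change signature calling, region
    annotation (TSS distance, CpG density, window-based gene association),
    transcription-factor motif scanning and binomial enrichment against
    size-matched background regions, motif-accessibility summaries, stage-trend
    tests, expression-accessibility correlations, a marker-gene quartile filter
    for excluding Basal-like tumors, and GSEA input tables. Ships a synthetic
    cohort generator with planted group, motif, stage and regulator structure
    so every stage of the pipeline is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    tools,
    methods,
    mclust,
    uwot,
    yaml,
    jsonlite
VignetteBuilder: knitr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
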