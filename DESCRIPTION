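Package: afmaturity
Title: Cell-Free Amniotic-Fluid Transcriptome Analysis of Fetal Maturity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cell-free RNA-seq profiles of amniotic fluid
    across gestational stages: trimmed-mean (TMM) between-sample normalization,
    stage-wise differential expression (one-way ANOVA with paired comparisons,
    Benjamini-Hochberg FDR, empirical-Bayes moderated t-tests for small
    morbidity subgroups, temporal trend classification by sign rule or a
    one-dimensional self-organizing map), tissue/cell-of-origin attribution of
    abundant transcripts against a multi-tissue expression atlas, hypergeometric
    marker-set enrichment, fetal-origin verification from XIST and Y-chromosome
    markers, and junction-based alternative-splicing analysis (reciprocal
    junction detection, percent-spliced-in estimation, group comparison, and
    reference-panel filtering). Includes a synthetic-study generator that
    plants known stage-monotone genes, tissue markers, sex signals and
    cassette-exon PSI shifts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
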