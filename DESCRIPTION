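Package: panpav
Title: Pangenome Gene Presence/Absence Variation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Map-to-pan analysis of gene presence/absence variation (PAV)
    in population genomics. Provides an iterative nonreference-sequence
    extraction loop over pairwise whole-genome alignments, coverage-based
    gene presence calling (minCov/lostCutoff rule), core/softcore/shell/cloud
    classification with saturation (rarefaction) curves, PCA on binary PAV
    matrices, Fisher's-exact gene-frequency selection tests, breed-specific
    gene detection, a two-haplotype genomic hybridization screen,
    PAV-GWAS by single-marker regression with Bonferroni control,
    gene-CDS-haplotype trait grouping, and expression-side utilities
    (FPKM, the TAU tissue-specificity index, PAV-class expression summaries,
    a simple two-group differential-expression test, coexpression pairing
    and variant-burden tables). A synthetic-data generator produces every
    input the pipeline consumes so the whole analysis is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
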