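Package: chromShade
Title: Chromatin Accessibility and Shade-Responsive Transcription Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for studying how shade-responsive
    transcription relates to chromatin accessibility and transcription-factor
    occupancy in plants. Builds replicate-supported consensus accessible
    chromatin regions from per-replicate ATAC-seq peak calls, annotates peaks
    to genes with strand-aware distance bins, calls transcription-factor target
    genes from ChIP peaks using TSS/TES windows, classifies binding sites as
    open or closed against accessible chromatin, performs negative-binomial
    likelihood-ratio differential testing of gene and region counts with
    Benjamini-Hochberg correction, and integrates differential accessibility
    with expression through row z-scoring and hierarchical clustering. A
    synthetic-data generator with planted ground truth (gene expression classes,
    accessible-region dynamics, open and closed binding sites, replicate peak
    jitter and false peaks) makes every stage testable without sequencing data.
    Also provides the exact arithmetic for RT-qPCR relative expression,
    ChIP-qPCR percent input, and chromatin-accessibility qPCR enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
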