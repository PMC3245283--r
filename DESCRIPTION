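Package: MethCapDMR
Title: Windowed Differential Methylation Analysis for MBD-Capture Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential methylation analysis for MBD/MethylCap sequencing of
    two conditions: fixed 500 bp genome tiling, per-window capture-read
    counting and reads-per-million normalization, differentially methylated
    region (DMR) calling under a three-part filter (rpm, rpm ratio, exact
    test p-value), genomic-feature and TSS-proximity annotation, CpG
    observed/expected profiling, hypergeometric term enrichment and gene-list
    overlap tests, plus a ground-truthed simulator of MBD-capture reads over
    a toy genome for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
biocViews: DNAMethylation, DifferentialMethylation, Sequencing, Coverage,
    Epigenetics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
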