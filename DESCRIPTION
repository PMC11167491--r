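Package: splicefreq
Title: Intron-Centered Alternative Splicing and Expression Quantification
    from Spliced RNA-seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers and quantifies introns from spliced RNA-seq
    alignments (SAM/BAM), computes intron-centered alternative-splicing
    statistics (RAS and RANS splicing ratios, major/minor-isoform
    classification), union-exon gene expression (FPKM and depth-weighted
    FPKM), per-sample sequencing depth over BUSCO genes, and a
    sample-subsampling saturation analysis.  Includes a fully synthetic
    ground-truthed data generator (genome, GFF3 annotation, per-sample SAM
    reads with known splicing fractions) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments
Config/testthat/edition: 3
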