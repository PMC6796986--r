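Package: skipedit
Title: Design and Quantification of Base-Editor-Induced Exon Skipping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for programming exon skipping with CRISPR base editors.
    Designs adenine (ABE) and cytidine (BE3) base-editor sgRNAs that disrupt
    the conserved AG dinucleotide of splice acceptors at inner exons,
    predicts position-dependent on-target editing efficiency, enumerates
    genome-wide off-target sites within two mismatches and scores guide
    specificity, and compares editor modes genome-wide. Quantifies A>G / T>C
    conversion from amplicon deep sequencing (quality trimming, primer
    demultiplexing, pileup windows, sequencing-error background estimation
    and one-sided binomial significance calls) and exon-skipping rates from
    RNA reads by splice-junction classification or from gel densitometry.
    Ships a deterministic synthetic-data generator emitting FASTA, GTF,
    FASTQ and SAM fixtures with exact ground truth, and a command-line
    interface over the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
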