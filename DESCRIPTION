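Package: tn5prefer
Title: Quantifying and Correcting Tn5 Transposase Insertion Preference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the sequence preference of the Tn5 transposase
    from ATAC-seq style data. Converts paired-end fragments to single-base
    insertion-event centers (+4/-5 shift onto the 9-bp target-site duplication),
    quantifies insertion enrichment across genomic feature sets with a
    chi-square observed/expected statistic under FDR control, builds a position
    weight matrix from center-aligned insertion windows and scans genomes with
    exact p-values, encodes 51-bp windows as DNA shape (pentamer lookup),
    per-position motif score and k-mer one-hot vectors for an elastic-net
    logistic classification framework, runs the context-dependent 9-mer
    procedure for DNA methylation effects, and corrects single-base insertion
    signal with a k-mer bias model. A synthetic-data generator with planted
    motif, dinucleotide and methylation preference supports validation by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
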