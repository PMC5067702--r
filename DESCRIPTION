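Package: ncontext
Title: Genomic-Context Target Annotation for Differentially Expressed Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for reusing time-course microarray expression data to
    associate differentially expressed non-coding RNAs (lincRNAs, antisense
    RNAs, pseudogenes) with putative protein-coding targets through genomic
    context. Differential expression is assessed per tissue and post-injury
    interval against a baseline with fold-change and t-test filters plus
    Benjamini-Hochberg control, probes are collapsed to genes, and three
    contextual procedures assign targets: neighborhood search within a fixed
    genomic window around lincRNA loci, opposite-strand overlap detection for
    antisense RNAs, and parental-gene assignment for pseudogenes via local
    sequence alignment. Target sets are projected onto protein-protein
    interaction networks with confidence filtering, and a generic
    hypergeometric over-representation test annotates them against
    user-supplied gene sets. A synthetic-data generator with a planted-truth
    manifest makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
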