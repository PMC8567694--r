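Package: rmscan
Title: Detecting Recently Mobile Transposable Element Subfamilies from
    Polymorphic Deletions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies recently mobile transposable element (TE)
    subfamilies (RMSs) in a reference genome from the overlap pattern
    between polymorphic deletions and human-specific TE instances. Each
    polymorphic deletion is complemented by flanking "pseudo-indels" of
    the same size, tiled with 50% overlap, which provide a local null
    model of chance TE-indel matches; per-subfamily match counts are
    compared with a one-sided Fisher's exact test and corrected by
    Benjamini-Hochberg FDR. Includes the surrounding pipeline: readers
    for RepeatMasker annotation, BED and VCF deletion call sets; the
    human-specificity filter from cross-genome mapped fractions;
    redundancy pruning of deletion catalogues via iterative max-degree
    removal on an overlap graph; subfamily-set and gene-proximity
    enrichment tests; genomic-context and cis-regulatory-element
    annotation of polymorphic mobile element insertions (pMEIs);
    post-processing of per-tile DNase-hypersensitivity model scores into
    predicted hypersensitive sites; and a synthetic-genome simulator with
    planted truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
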