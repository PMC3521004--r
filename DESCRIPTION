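Package: curliscan
Title: Annotation of Curli Functional-Amyloid (csg) Systems in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and annotates curli functional-amyloid (csg) systems in
    bacterial proteomes and genome annotations. Builds profile hidden Markov
    models from curated seed alignments and searches proteomes with them,
    scans proteins for the 22-residue minimalistic curli repeat motif
    (X6QXGX2NX10) including superimposed (overlapping) repeats, classifies
    csg operon architectures from gene coordinates, runs an iterative
    search-and-curation loop to convergence, computes validation statistics
    against truth sets, and compares Csg protein trees with 16S trees via
    neighbor joining and Robinson-Foulds distances. Ships a synthetic-genome
    generator with planted truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
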