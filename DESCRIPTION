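Package: splicewalk
Title: Two-Pass Spliced Alignment of Noisy Long RNA-seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-pass spliced aligner for error-prone long RNA-seq reads
    (PacBio and Oxford Nanopore). A de Bruijn graph unitig index of the
    reference genome drives a first alignment pass that chains maximal exact
    matches into per-read alignment skeletons; skeletons are pooled across all
    reads to infer exonic regions, whose boundaries are refined with
    donor/acceptor splice-site scoring; inferred exons are stitched into local
    spliced reference sequences against which each read receives a base-level
    spliced alignment with an intron-aware CIGAR. Ships with a synthetic
    genome/transcriptome/long-read simulator covering four named error models
    and the full ground-truth and annotation-based evaluation metric suite, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
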