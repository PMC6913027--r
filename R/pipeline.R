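## Pipeline wiring: a single configuration object and the three-step
## two-pass alignment over a whole read set (pass 1 skeletons for every
## read; pooled exon inference, optionally annotation-assisted; pass 2
## refined alignment per read). Reads are independent within each pass;
## exon inference is a serial barrier between the passes.

#' Pipeline configuration
#'
#' Collects the tunable parameters of all pipeline stages and re-validates
#' their constraints.
#'
#' @param k index k-mer size (default 22).
#' @param l first-pass seed length, l < k (default 15).
#' @param m seed stride (default 5).
#' @param s second-pass short seed length, s < l (default 8).
#' @param T_intron maximum intron length in bp (default 200000).
#' @param epsilon secondary-skeleton score threshold (default 0.05).
#' @param max_skeletons cap on skeletons per read (default 5).
#' @param bridge intra-exon gap bridging in projection (default 20).
#' @param join_gap draft-exon merge gap (default 10).
#' @param min_len,min_cov draft exon filters (defaults 10 bp, 1 read).
#' @param W splice-site refinement window half-width (default 15).
#' @param taper_in,taper_out splice-site positional tapers for candidates
#'   interior/exterior to the draft exon (defaults 0.5, 0.05).
#' @param D_min large-deletion excision threshold (default 30).
#' @param min_exon_m micro-exon cleanup threshold: minimum aligned bases
#'   for an exon segment of the final CIGAR to survive (default 8).
#' @param scoring an [align_scoring()] object.
#' @param repeat_cap repetitive-unitig occurrence cap (default 300).
#' @param corridor_pad second-pass corridor padding (default 20000).
#' @param single_pass disable exon inference and build LSRSs from anchor
#'   MBs only (ablation mode).
#' @param seed RNG seed recorded for provenance (the aligner itself is
#'   deterministic).
#' @param verbose emit per-stage progress messages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 22L, l = 15L, m = 5L, s = 8L,
                            T_intron = 200000L, epsilon = 0.05,
                            max_skeletons = 5L, bridge = 20L,
                            join_gap = 10L, min_len = 10L, min_cov = 1,
                            W = 15L, taper_in = 0.5, taper_out = 0.05,
                            D_min = 30L, min_exon_m = 8L,
                            scoring = align_scoring(), repeat_cap = 300L,
                            corridor_pad = 20000L, single_pass = FALSE,
                            seed = 1L, verbose = FALSE) {
  stopifnot(k >= 3, k <= 31, l >= 2, l < k, m >= 1, s >= 2, s < l,
            T_intron > 0, epsilon >= 0, epsilon < 1, W >= 0, D_min > 0,
            inherits(scoring, "align_scoring"))
  structure(list(k = as.integer(k), l = as.integer(l), m = as.integer(m),
                 s = as.integer(s), T_intron = as.integer(T_intron),
                 epsilon = epsilon, max_skeletons = as.integer(max_skeletons),
                 bridge = as.integer(bridge), join_gap = as.integer(join_gap),
                 min_len = as.integer(min_len), min_cov = min_cov,
                 W = as.integer(W), taper_in = taper_in, taper_out = taper_out,
                 D_min = as.integer(D_min),
                 min_exon_m = as.integer(min_exon_m),
                 scoring = scoring, repeat_cap = as.integer(repeat_cap),
                 corridor_pad = as.integer(corridor_pad),
                 single_pass = isTRUE(single_pass), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Two-pass alignment of a read set
#'
#' Pass 1 computes alignment skeletons for every read; the pooled skeletons
#' (plus annotated isoforms, when a `gene_annotation` is given) drive exon
#' inference; pass 2 aligns each read against its stitched local spliced
#' reference. Every input read appears exactly once as a primary or
#' unmapped record; additional near-best placements are emitted as
#' secondary records. The result is deterministic given inputs and
#' configuration.
#'
#' @param reference named character vector of chromosome sequences (or a
#'   FASTA path).
#' @param reads read data.frame from [read_reads()] (or a FASTA/FASTQ
#'   path).
#' @param config a [pipeline_config()].
#' @param annotation optional `gene_annotation` (or GTF path).
#' @param index optional pre-built [build_index()] result.
#' @param sam_out optional path: write the alignments as SAM.
#' @return data.frame of SAM-ready alignment records; the inferred exon
#'   table is attached as attribute `"exons"`.
#' @export
align_all <- function(reference, reads, config = pipeline_config(),
                      annotation = NULL, index = NULL, sam_out = NULL) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) reference <- read_fasta(reference)
  if (is.character(reads) && length(reads) == 1) reads <- read_reads(reads)
  if (is.character(annotation)) annotation <- read_gtf(annotation)
  if (is.null(index))
    index <- build_index(reference, k = config$k, l = config$l,
                         repeat_cap = config$repeat_cap)
  n <- nrow(reads)
  if (config$verbose) message("pass 1: skeletons for ", n, " reads")
  skels <- vector("list", n)
  for (i in seq_len(n)) {
    skels[[i]] <- read_skeletons(index, reads$seq[i], m = config$m,
                                 T_intron = config$T_intron,
                                 epsilon = config$epsilon,
                                 max_skeletons = config$max_skeletons)
  }
  exons <- NULL
  if (!config$single_pass) {
    flat <- unlist(skels, recursive = FALSE)
    if (config$verbose)
      message("exon inference over ", length(flat), " skeletons")
    if (length(flat) > 0 || !is.null(annotation)) {
      model <- splice_model(W = config$W, taper_in = config$taper_in,
                            taper_out = config$taper_out)
      exons <- infer_exons(flat, reference, annotation = annotation,
                           bridge = config$bridge,
                           join_gap = config$join_gap,
                           min_len = config$min_len,
                           min_cov = config$min_cov, model = model)
      if (config$verbose) message(nrow(exons), " refined exon regions")
    }
  }
  if (config$verbose) message("pass 2: refined alignment")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rid <- reads$id[i]; seq <- reads$seq[i]
    qual <- if (!is.null(reads$qual)) reads$qual[i] else NA_character_
    cands <- align_read(seq, skels[[i]], exons, reference,
                        scoring = config$scoring, s = config$s,
                        D_min = config$D_min,
                        corridor_pad = config$corridor_pad,
                        min_exon_m = config$min_exon_m)
    if (nrow(cands) == 0) {
      out[[i]] <- data.frame(qname = rid, flag = 4L, chrom = "*", pos = 0L,
                             mapq = 0L, cigar = "*", seq = seq, qual = qual,
                             score = NA_real_, stringsAsFactors = FALSE)
    } else {
      flags <- ifelse(cands$is_primary, 0L, 256L) +
        ifelse(cands$strand == "-", 16L, 0L)
      seqs <- ifelse(cands$strand == "-", revcomp(seq), seq)
      quals <- if (is.na(qual)) rep(NA_character_, nrow(cands))
               else ifelse(cands$strand == "-",
                           vapply(qual, function(q) paste(rev(strsplit(
                             q, "")[[1]]), collapse = ""), character(1)),
                           qual)
      out[[i]] <- data.frame(qname = rid, flag = flags, chrom = cands$chrom,
                             pos = cands$pos, mapq = cands$mapq,
                             cigar = cands$cigar, seq = seqs, qual = quals,
                             score = cands$score, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(qname = character(0), flag = integer(0),
                      chrom = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), qual = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "exons") <- exons
  if (!is.null(sam_out)) write_sam(res, reference, sam_out)
  res
}

#' Measure the realized per-read error rate of simulated reads
#'
#' Reconstructs each read's error-free source sequence from its truth
#' record (the concatenated genomic exon substrings, oriented with the
#' read) and computes the unit-cost edit distance normalised by alignment
#' columns, using an adaptive band that doubles until the distance is
#' stable.
#'
#' @param reads read data.frame.
#' @param truth matching truth data.frame.
#' @param reference named character vector of chromosome sequences.
#' @return numeric vector of per-read error rates (fractions).
#' @export
read_error_rate <- function(reads, truth, reference) {
  truth <- truth[match(reads$id, truth$read_id), , drop = FALSE]
  vapply(seq_len(nrow(reads)), function(i) {
    tex <- truth_exons(truth$exons[i])
    src <- paste(substring(reference[[truth$chrom[i]]], tex$start + 1L,
                           tex$end), collapse = "")
    q <- if (truth$strand[i] == "+") reads$seq[i] else revcomp(reads$seq[i])
    band <- max(64L, abs(nchar(src) - nchar(q)) + 64L)
    st <- cpp_edit_stats(q, src, band)
    repeat {
      band <- band * 2L
      st2 <- cpp_edit_stats(q, src, band)
      if (st2[1] == st[1]) break
      st <- st2
    }
    st2[1] / st2[2]
  }, numeric(1))
}
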