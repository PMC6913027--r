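## Exon inference: alignment skeletons from the whole read set are projected
## onto the genome as a coverage profile, covered regions are combined into
## draft exons (optionally merged with annotated exons), short/low-coverage
## drafts are filtered, and boundaries are refined by donor/acceptor
## splice-site scoring in small flanking windows.

#' Project alignment skeletons to a genomic coverage profile
#'
#' Every MB of every skeleton increments the per-position count over its
#' genome footprint. Gaps between consecutive MBs of one skeleton shorter
#' than `bridge` bp are counted too: they are putative intra-exon scoring
#' gaps, not introns.
#'
#' @param skeletons flat list of skeletons (each with `chrom` and `mbs`).
#' @param bridge intra-exon gap bridging threshold in bp (default 20).
#' @param chrom_lens optional named vector of chromosome lengths; inferred
#'   from the skeletons when absent.
#' @return object of class `coverage_profile`: a named list of per-chromosome
#'   coverage Rle vectors.
#' @export
project_skeletons <- function(skeletons, bridge = 20L, chrom_lens = NULL) {
  starts <- list(); ends <- list()
  for (sk in skeletons) {
    mb <- sk$mbs
    chrom <- sk$chrom
    s <- mb$gs; e <- mb$ge
    if (nrow(mb) > 1) {
      gap_s <- mb$ge[-nrow(mb)]
      gap_e <- mb$gs[-1]
      keep <- gap_e > gap_s & (gap_e - gap_s) < bridge
      s <- c(s, gap_s[keep]); e <- c(e, gap_e[keep])
    }
    starts[[chrom]] <- c(starts[[chrom]], s)
    ends[[chrom]] <- c(ends[[chrom]], e)
  }
  chroms <- names(starts)
  if (is.null(chrom_lens))
    chrom_lens <- setNames(vapply(chroms, function(ch) max(ends[[ch]]),
                                  numeric(1)), chroms)
  cov <- lapply(chroms, function(ch) {
    IRanges::coverage(IRanges::IRanges(starts[[ch]] + 1L, ends[[ch]]),
                      width = chrom_lens[[ch]])
  })
  names(cov) <- chroms
  structure(list(cov = cov, chrom_lens = chrom_lens),
            class = "coverage_profile")
}

## Mean coverage of a 0-based half-open interval under a profile.
profile_mean <- function(profile, chrom, start, end) {
  r <- profile$cov[[chrom]]
  if (is.null(r)) return(0)
  n <- length(r)
  s <- min(start + 1L, n); e <- min(end, n)
  if (e < s) return(0)
  sum(as.numeric(S4Vectors::window(r, s, e))) / (end - start)
}

#' Combine covered regions (and annotated exons) into draft exons
#'
#' Maximal runs of positions with skeleton coverage >= 1 become candidate
#' regions; runs separated by less than `join_gap` bp are merged. When an
#' annotation is supplied, each annotated exon is injected as an
#' annotation-source region and merged with any overlapping read-derived
#' region (source becomes "both"); injecting annotation never removes a
#' read-derived region.
#'
#' @param profile a `coverage_profile`.
#' @param annotation optional `gene_annotation`.
#' @param join_gap merge gap in bp (default 10).
#' @return data.frame of draft exons: chrom, start, end, coverage, source.
#' @export
combine_regions <- function(profile, annotation = NULL, join_gap = 10L) {
  out <- list()
  anno_ex <- if (!is.null(annotation)) annotation$exons else NULL
  chroms <- union(names(profile$cov), unique(anno_ex$chrom))
  for (ch in chroms) {
    read_ir <- IRanges::IRanges()
    r <- profile$cov[[ch]]
    if (!is.null(r)) {
      read_ir <- IRanges::reduce(as(S4Vectors::Rle(as.vector(r) >= 1),
                                    "IRanges"),
                                 min.gapwidth = join_gap)
    }
    anno_ir <- IRanges::IRanges()
    if (!is.null(anno_ex)) {
      ae <- anno_ex[anno_ex$chrom == ch, , drop = FALSE]
      if (nrow(ae) > 0)
        anno_ir <- IRanges::reduce(IRanges::IRanges(ae$start + 1L, ae$end))
    }
    comb <- IRanges::reduce(c(read_ir, anno_ir))
    if (length(comb) == 0) next
    from_read <- IRanges::overlapsAny(comb, read_ir)
    from_anno <- IRanges::overlapsAny(comb, anno_ir)
    src <- ifelse(from_read & from_anno, "both",
                  ifelse(from_anno, "annotation", "reads"))
    df <- data.frame(chrom = ch, start = IRanges::start(comb) - 1L,
                     end = IRanges::end(comb), coverage = NA_real_,
                     source = src, stringsAsFactors = FALSE)
    df$coverage <- vapply(seq_len(nrow(df)), function(i)
      profile_mean(profile, ch, df$start[i], df$end[i]), numeric(1))
    out[[ch]] <- df
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), coverage = numeric(0),
                      source = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Filter draft exons on length and coverage
#'
#' @param drafts data.frame from [combine_regions()].
#' @param min_len minimum draft length in bp (default 10).
#' @param min_cov minimum mean skeleton coverage (default 1);
#'   annotation-sourced drafts are exempt.
#' @return filtered data.frame.
#' @export
filter_draft_exons <- function(drafts, min_len = 10L, min_cov = 1) {
  keep <- (drafts$end - drafts$start) >= min_len &
    (drafts$coverage >= min_cov | drafts$source == "annotation")
  out <- drafts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct the donor/acceptor splice scoring model
#'
#' A log-odds position-weight model over the canonical splice dinucleotides:
#' the acceptor window rewards AG ending immediately before the exon start
#' and the donor window rewards GT starting immediately after the exon end
#' (+1 per canonical base, -1 otherwise), with a small positional taper
#' pulling ties toward the draft boundary. Both orientations (GT-AG and
#' CT-AC) are scored; the better-scoring orientation assigns the region's
#' transcriptional strand.
#'
#' @param W window half-width in bp (default 15).
#' @param taper_in per-bp penalty for candidate boundaries inside the draft
#'   exon (default 0.5). Skeleton coverage biases draft boundaries inward
#'   (exact matches start late and end early under noise), so a true splice
#'   site is almost never interior to the draft; interior candidates are
#'   therefore heavily tapered.
#' @param taper_out per-bp penalty for candidates outside the draft exon
#'   (default 0.05): outward shifts are cheap because an over-extended exon
#'   segment is recovered downstream (unsupported reference bases next to a
#'   junction are absorbed into the intron).
#' @param path optional TSV file with columns `signal`
#'   (acceptor_fwd/donor_fwd/acceptor_rev/donor_rev) and `dinuc`,
#'   substituting the canonical dinucleotides.
#' @return object of class `splice_model`.
#' @export
splice_model <- function(W = 15L, taper_in = 0.5, taper_out = 0.05,
                         path = NULL) {
  sig <- c(acceptor_fwd = "AG", donor_fwd = "GT",
           acceptor_rev = "AC", donor_rev = "CT")
  if (!is.null(path)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    sig[tab$signal] <- toupper(tab$dinuc)
  }
  structure(list(W = as.integer(W), taper_in = taper_in,
                 taper_out = taper_out, signals = sig),
            class = "splice_model")
}

## positional penalty of a candidate boundary: `d` is the signed offset from
## the draft boundary where positive means toward the exon interior.
## Coverage overshoots the true boundary by 1-3 bp routinely (chance match
## extension), so the first 3 interior bp are tapered gently; deeper
## interior candidates pay the full rate.
boundary_taper <- function(model, d) {
  ifelse(d > 0,
         pmin(d, 3) * model$taper_out + pmax(d - 3, 0) * model$taper_in,
         -model$taper_out * d)
}

## Dinucleotide log-odds score (+1 matching base, -1 otherwise) of the
## 2-mer of `seq` starting at 0-based position p against `expect`.
dinuc_score <- function(seq, p, expect) {
  if (p < 0 || p + 2 > nchar(seq)) return(-2)
  d <- substr(seq, p + 1, p + 2)
  sum(ifelse(strsplit(d, "")[[1]] == strsplit(expect, "")[[1]], 1, -1))
}

#' Refine draft exon boundaries with splice-site scoring
#'
#' For each draft exon, candidate acceptor positions in the window of
#' half-width `W` around the draft start and donor positions around the
#' draft end are scored with the model; the argmax positions become the
#' refined boundaries. Ties break toward the draft boundary. If refinement
#' would produce an empty exon, the draft interval is kept unchanged.
#'
#' @param drafts data.frame of draft exons.
#' @param reference named character vector of chromosome sequences.
#' @param model a `splice_model` (default `splice_model()`).
#' @return data.frame of refined exon regions with acceptor/donor scores
#'   and inferred transcriptional strand.
#' @export
refine_boundaries <- function(drafts, reference, model = splice_model()) {
  W <- model$W
  n <- nrow(drafts)
  out <- drafts
  out$strand <- rep("+", n)
  out$acc_score <- out$don_score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    seq <- reference[[drafts$chrom[i]]]
    clen <- nchar(seq)
    ds <- drafts$start[i]; de <- drafts$end[i]
    sw <- max(0L, ds - W):min(clen, ds + W)
    ew <- max(0L, de - W):min(clen, de + W)
    ## The acceptor dinucleotide (intron end) occupies the two positions
    ## immediately before the exon start; the donor dinucleotide (intron
    ## start) the two immediately after the exon end. Positions beyond the
    ## draft start / before the draft end are exon-interior. Each boundary
    ## is scored with the better of the two orientations\' signals, so a
    ## weak signal pair on one strand can never displace a perfect splice
    ## site seen on the other.
    sa_f <- vapply(sw, function(p)
      dinuc_score(seq, p - 2L, model$signals[["acceptor_fwd"]]), numeric(1))
    sa_r <- vapply(sw, function(p)
      dinuc_score(seq, p - 2L, model$signals[["acceptor_rev"]]), numeric(1))
    sd_f <- vapply(ew, function(p)
      dinuc_score(seq, p, model$signals[["donor_fwd"]]), numeric(1))
    sd_r <- vapply(ew, function(p)
      dinuc_score(seq, p, model$signals[["donor_rev"]]), numeric(1))
    sa <- pmax(sa_f, sa_r) - boundary_taper(model, sw - ds)
    sd <- pmax(sd_f, sd_r) - boundary_taper(model, de - ew)
    a_ord <- order(-sa, abs(sw - ds))
    d_ord <- order(-sd, abs(ew - de))
    a <- sw[a_ord[1]]; d <- ew[d_ord[1]]
    if (d > a) {
      out$start[i] <- a
      out$end[i] <- d
    }
    out$strand[i] <- if (sum(pmax(sa_f, 0)) + sum(pmax(sd_f, 0)) >=
                           sum(pmax(sa_r, 0)) + sum(pmax(sd_r, 0)))
      "+" else "-"
    out$acc_score[i] <- sa[a_ord[1]]
    out$don_score[i] <- sd[d_ord[1]]
  }
  out
}

#' Infer exon regions from pooled alignment skeletons
#'
#' Convenience wrapper running projection, combination, filtering and
#' boundary refinement in sequence.
#'
#' @param skeletons flat list of skeletons from the full read set.
#' @param reference named character vector of chromosome sequences.
#' @param annotation optional `gene_annotation`.
#' @param bridge,join_gap,min_len,min_cov,model tuning parameters; see the
#'   individual steps.
#' @return data.frame of refined exon regions.
#' @export
infer_exons <- function(skeletons, reference, annotation = NULL,
                        bridge = 20L, join_gap = 10L, min_len = 10L,
                        min_cov = 1, model = splice_model()) {
  profile <- project_skeletons(skeletons, bridge = bridge,
                               chrom_lens = setNames(nchar(reference),
                                                     names(reference)))
  drafts <- combine_regions(profile, annotation = annotation,
                            join_gap = join_gap)
  drafts <- filter_draft_exons(drafts, min_len = min_len, min_cov = min_cov)
  refine_boundaries(drafts, reference, model = model)
}
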