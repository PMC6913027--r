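## Evaluation: ground-truth metrics (Base%, Exon%, Read80%, Read100%) from
## SAM + truth TSV, and annotation-based metrics (#BaseA, #BaseGA, #ExonP,
## #ExonGO, #ExonGA, #ExonGA(x), #ReadGA) from SAM + GTF. Only primary
## alignments are evaluated; unmapped reads stay in the denominators.

#' Predicted exons of one spliced alignment
#'
#' Maximal reference-consuming runs between N operations (M and D merged,
#' I ignored), as 0-based half-open genome intervals.
#'
#' @param pos 0-based alignment start.
#' @param cigar spliced CIGAR string.
#' @return data.frame with columns start, end.
#' @export
predicted_exons <- function(pos, cigar) {
  co <- cigar_ops(cigar)
  starts <- integer(0); ends <- integer(0)
  g <- pos
  open_s <- NA_integer_
  for (i in seq_len(nrow(co))) {
    op <- co$op[i]; len <- co$len[i]
    if (op %in% c("M", "D", "=", "X")) {
      if (is.na(open_s)) open_s <- g
      g <- g + len
    } else if (op == "N") {
      if (!is.na(open_s)) { starts <- c(starts, open_s); ends <- c(ends, g) }
      g <- g + len
      open_s <- NA_integer_
    }
    ## I and S consume no reference
  }
  if (!is.na(open_s)) { starts <- c(starts, open_s); ends <- c(ends, g) }
  data.frame(start = starts, end = ends)
}

## Greedy one-to-one matching of predicted to truth exons in genomic order.
match_exons <- function(truth, pred, tol = 5L) {
  ti <- 1L; pi <- 1L; nt <- 0L
  while (ti <= nrow(truth) && pi <= nrow(pred)) {
    ds <- abs(truth$start[ti] - pred$start[pi])
    de <- abs(truth$end[ti] - pred$end[pi])
    if (ds <= tol && de <= tol) {
      nt <- nt + 1L; ti <- ti + 1L; pi <- pi + 1L
    } else if (truth$start[ti] < pred$start[pi]) {
      ti <- ti + 1L
    } else {
      pi <- pi + 1L
    }
  }
  nt
}

#' Ground-truth alignment metrics on simulated reads
#'
#' Base%: proportion of read bases (with a ground-truth genome position)
#' mapped within `tol` bp of that position; unaligned reads keep their
#' bases in the denominator. Exon%: proportion of ground-truth exons whose
#' both predicted boundaries lie within `tol` bp. Read80%: reads with
#' N_T/N_G > 80% and N_T/N_P > 80% (strict); Read100%: both ratios exactly
#' 100%. A predicted exon is a true positive iff a truth exon matches both
#' boundaries within `tol`, one-to-one greedily in genomic order.
#'
#' @param sam alignment data.frame from [read_sam()] (or a path to a SAM
#'   file).
#' @param truth truth data.frame from [read_truth()] (or a path).
#' @param tol boundary/base tolerance in bp (default 5).
#' @return list of class `sim_metrics`: base_pct, exon_pct, read80_pct,
#'   read100_pct and a per-read detail data.frame (N_G, N_P, N_T).
#' @export
sim_metrics <- function(sam, truth, tol = 5L) {
  if (is.character(sam)) sam <- read_sam(sam)
  if (is.character(truth)) truth <- read_truth(truth)
  primary <- sam[bitwAnd(sam$flag, 256L) == 0L, , drop = FALSE]
  missing <- setdiff(primary$qname, truth$read_id)
  if (length(missing))
    stop("missing truth record for read(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  prim <- primary[match(truth$read_id, primary$qname), , drop = FALSE]

  base_good <- 0; base_tot <- 0
  n_g <- integer(nrow(truth)); n_p <- integer(nrow(truth))
  n_t <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tex <- truth_exons(truth$exons[i])
    tstart <- tex$start[1]
    tpos <- cigar_base_positions(tstart, truth$cigar[i])
    base_tot <- base_tot + sum(!is.na(tpos))
    n_g[i] <- nrow(tex)
    rec <- prim[i, ]
    mapped <- !is.na(rec$qname) && bitwAnd(rec$flag, 4L) == 0L &&
      rec$chrom == truth$chrom[i]
    if (mapped) {
      ppos <- cigar_base_positions(rec$pos, rec$cigar)
      if (length(ppos) == length(tpos)) {
        ok <- !is.na(tpos) & !is.na(ppos) & abs(tpos - ppos) <= tol
        base_good <- base_good + sum(ok)
      }
      pex <- predicted_exons(rec$pos, rec$cigar)
      n_p[i] <- nrow(pex)
      n_t[i] <- match_exons(tex, pex, tol = tol)
    }
  }
  read80 <- n_p > 0 & n_t / n_g > 0.8 & n_t / n_p > 0.8
  read100 <- n_p > 0 & n_t == n_g & n_t == n_p
  structure(list(
    base_pct = if (base_tot > 0) base_good / base_tot else NA_real_,
    exon_pct = sum(n_t) / sum(n_g),
    read80_pct = mean(read80),
    read100_pct = mean(read100),
    detail = data.frame(read_id = truth$read_id, N_G = n_g, N_P = n_p,
                        N_T = n_t, read80 = read80, read100 = read100,
                        stringsAsFactors = FALSE)),
    class = "sim_metrics")
}

#' @export
print.sim_metrics <- function(x, ...) {
  cat(sprintf("Base%%: %.4f  Exon%%: %.4f  Read80%%: %.4f  Read100%%: %.4f\n",
              x$base_pct, x$exon_pct, x$read80_pct, x$read100_pct))
  invisible(x)
}

#' Annotation-based alignment metrics
#'
#' #BaseA: aligned (M) bases of primary alignments. #BaseGA: aligned bases
#' falling inside annotated exons. #ExonP: predicted exons. #ExonGO:
#' predicted exons overlapping an annotated exon by at least
#' `min_overlap` bp. #ExonGA: predicted exons with both boundaries within
#' `tol` bp of one annotated exon. #ExonGA(x): exactly matched exons
#' shorter than x bp. #ReadGA: reads whose every intron boundary lies
#' within `tol` bp of an annotated exon boundary (an unspliced read
#' satisfies the condition vacuously; set `count_unspliced = FALSE` to
#' require at least one junction).
#'
#' @param sam alignment data.frame from [read_sam()] (or a path).
#' @param annotation a `gene_annotation` (or a path to a GTF).
#' @param xs length cutoffs for ExonGA(x) (default c(20, 30, 40, 50, 60)).
#' @param tol boundary tolerance (default 5).
#' @param min_overlap ExonGO overlap requirement (default 10).
#' @param count_unspliced whether junction-free reads count as ReadGA
#'   (default TRUE).
#' @return list of class `anno_metrics` with the counts above.
#' @export
anno_metrics <- function(sam, annotation, xs = c(20L, 30L, 40L, 50L, 60L),
                         tol = 5L, min_overlap = 10L,
                         count_unspliced = TRUE) {
  if (is.character(sam)) sam <- read_sam(sam)
  if (is.character(annotation)) annotation <- read_gtf(annotation)
  ex <- unique(annotation$exons[, c("chrom", "start", "end")])
  recs <- sam[bitwAnd(sam$flag, 256L) == 0L & bitwAnd(sam$flag, 4L) == 0L, ,
              drop = FALSE]
  bad <- setdiff(unique(recs$chrom), unique(ex$chrom))
  if (length(bad))
    stop("chromosome(s) in SAM absent from annotation: ",
         paste(bad, collapse = ", "))

  baseA <- 0; baseGA <- 0
  exonP <- 0L; exonGO <- 0L; exonGA <- 0L
  ga_len <- integer(0)
  readGA <- 0L
  for (ch in unique(recs$chrom)) {
    ae <- ex[ex$chrom == ch, , drop = FALSE]
    air <- IRanges::IRanges(ae$start + 1L, ae$end)
    air_red <- IRanges::reduce(air)
    rr <- recs[recs$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(rr))) {
      co <- cigar_ops(rr$cigar[i])
      ## M-run genome intervals (D excluded) for base counting
      g <- rr$pos[i]
      ms <- integer(0); me <- integer(0)
      for (j in seq_len(nrow(co))) {
        if (co$op[j] %in% c("M", "=", "X")) {
          ms <- c(ms, g); me <- c(me, g + co$len[j]); g <- g + co$len[j]
        } else if (co$op[j] %in% c("D", "N")) g <- g + co$len[j]
      }
      baseA <- baseA + sum(me - ms)
      mir <- IRanges::IRanges(ms + 1L, me)
      ov <- IRanges::findOverlaps(mir, air_red)
      if (length(ov))
        baseGA <- baseGA + sum(IRanges::width(IRanges::pintersect(
          mir[S4Vectors::queryHits(ov)], air_red[S4Vectors::subjectHits(ov)])))
      pex <- predicted_exons(rr$pos[i], rr$cigar[i])
      exonP <- exonP + nrow(pex)
      ok_junc <- TRUE
      for (p in seq_len(nrow(pex))) {
        pir <- IRanges::IRanges(pex$start[p] + 1L, pex$end[p])
        ov <- IRanges::findOverlaps(pir, air)
        if (length(ov)) {
          w <- IRanges::width(IRanges::pintersect(
            rep(pir, length(ov)), air[S4Vectors::subjectHits(ov)]))
          if (max(w) >= min_overlap) exonGO <- exonGO + 1L
        }
        hit <- any(abs(ae$start - pex$start[p]) <= tol &
                     abs(ae$end - pex$end[p]) <= tol)
        if (hit) {
          exonGA <- exonGA + 1L
          ga_len <- c(ga_len, pex$end[p] - pex$start[p])
        }
      }
      if (nrow(pex) > 1) {
        for (p in seq_len(nrow(pex) - 1)) {
          left_ok <- any(abs(ae$end - pex$end[p]) <= tol)
          right_ok <- any(abs(ae$start - pex$start[p + 1]) <= tol)
          if (!(left_ok && right_ok)) { ok_junc <- FALSE; break }
        }
        if (ok_junc) readGA <- readGA + 1L
      } else if (count_unspliced) {
        readGA <- readGA + 1L
      }
    }
  }
  ga_by_len <- setNames(vapply(xs, function(x) sum(ga_len < x), integer(1)),
                        paste0("ExonGA(", xs, ")"))
  structure(list(baseA = baseA, baseGA = baseGA, exonP = exonP,
                 exonGO = exonGO, exonGA = exonGA,
                 exonGA_by_len = ga_by_len, readGA = readGA),
            class = "anno_metrics")
}

#' @export
print.anno_metrics <- function(x, ...) {
  cat(sprintf("#BaseA: %d  #BaseGA: %d\n#ExonP: %d  #ExonGO: %d  #ExonGA: %d\n",
              x$baseA, x$baseGA, x$exonP, x$exonGO, x$exonGA))
  cat(paste(names(x$exonGA_by_len), x$exonGA_by_len, collapse = "  "), "\n")
  cat(sprintf("#ReadGA: %d\n", x$readGA))
  invisible(x)
}
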