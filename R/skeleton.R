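## First-pass alignment: l-mer seeds are matched to the unitigs of the RdBG,
## extended in both directions into U-MEMs, merged along diagonals into
## SU-MEMs, projected through unitig occurrence runs onto the genome as
## match blocks (MBs), and chained by sparse dynamic programming into one or
## more per-read alignment skeletons.

#' Extract l-mer seeds from a read
#'
#' Seeds are taken every `m` bases starting at offset 0; seeds containing N
#' are omitted. A read shorter than `l` yields no seeds.
#'
#' @param seq read sequence.
#' @param l seed length (default 15).
#' @param m seed stride in bp (default 5).
#' @return data.frame with columns `offset` (0-based) and `seed`.
#' @export
extract_seeds <- function(seq, l = 15L, m = 5L) {
  stopifnot(l >= 2, m >= 1)
  n <- nchar(seq)
  if (n < l) return(data.frame(offset = integer(0), seed = character(0)))
  offs <- seq(0L, n - l, by = m)
  seeds <- substring(seq, offs + 1L, offs + l)
  keep <- !grepl("N", seeds, fixed = TRUE)
  data.frame(offset = offs[keep], seed = seeds[keep],
             stringsAsFactors = FALSE)
}

#' Find U-MEMs between a read and the unitigs of the index
#'
#' Every seed hit is extended base-by-base in both directions within the
#' read and the unitig until mismatch or boundary; duplicates discovered
#' from multiple seeds are collapsed; hits on highly repetitive unitigs are
#' skipped.
#'
#' @param index an `rdbg_index`.
#' @param seq read sequence.
#' @param m seed stride (default 5).
#' @return data.frame with columns rs, re (read interval, 0-based half-open),
#'   uid (1-based), us, ue (unitig interval).
#' @export
find_umems <- function(index, seq, m = 5L) {
  mat <- cpp_find_umems(index_ptr(index), toupper(seq), as.integer(m))
  data.frame(rs = mat[, 1], re = mat[, 2], uid = mat[, 3] + 1L,
             us = mat[, 4], ue = mat[, 5])
}

#' Merge co-linear same-diagonal U-MEMs into SU-MEMs
#'
#' U-MEMs on the same unitig with equal diagonal offset (us - rs) separated
#' by at most `slack` bases on the read are merged into one block spanning
#' min start to max end; all others pass through unchanged.
#'
#' @param umems data.frame as returned by [find_umems()].
#' @param slack maximum read gap bridged by a merge (default 2 bp).
#' @return data.frame of SU-MEMs with the same columns.
#' @export
merge_sumems <- function(umems, slack = 2L) {
  if (nrow(umems) == 0) return(umems)
  u <- umems
  u$diag <- u$us - u$rs
  u <- u[order(u$uid, u$diag, u$rs), ]
  out <- u[1, , drop = FALSE]
  if (nrow(u) > 1) for (i in 2:nrow(u)) {
    last <- nrow(out)
    if (u$uid[i] == out$uid[last] && u$diag[i] == out$diag[last] &&
        u$rs[i] - out$re[last] <= slack) {
      out$re[last] <- max(out$re[last], u$re[i])
      out$ue[last] <- max(out$ue[last], u$ue[i])
    } else {
      out <- rbind(out, u[i, , drop = FALSE])
    }
  }
  out$diag <- NULL
  rownames(out) <- NULL
  out
}

#' Project SU-MEMs onto the genome as match blocks
#'
#' Each SU-MEM yields one MB per unitig occurrence run that (at least
#' partially) covers its unitig interval; partial coverage clips the block
#' on both the read and the genome so the substring-equality invariant
#' holds.
#'
#' @param index an `rdbg_index`.
#' @param sumems data.frame of (S)U-MEMs.
#' @param strand strand label attached to the MBs ("+" or "-").
#' @param min_len minimum clipped block length kept (default `index$l`).
#' @return data.frame with columns rs, re, chrom, gs, ge, strand.
#' @export
project_to_mbs <- function(index, sumems, strand = "+", min_len = NULL) {
  if (is.null(min_len)) min_len <- index$l
  if (nrow(sumems) == 0)
    return(data.frame(rs = integer(0), re = integer(0),
                      chrom = character(0), gs = integer(0),
                      ge = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  k <- index$k
  occ <- index$occ[index$occ$uid %in% sumems$uid, , drop = FALSE]
  occ_by_uid <- split(occ, occ$uid)
  res <- vector("list", nrow(sumems))
  for (i in seq_len(nrow(sumems))) {
    s <- sumems[i, ]
    runs <- occ_by_uid[[as.character(s$uid)]]
    if (is.null(runs)) next
    span_s <- runs$uoff
    span_e <- runs$uoff + runs$nk + k - 1L
    a <- pmax(s$us, span_s)
    b <- pmin(s$ue, span_e)
    keep <- which(b - a >= min_len)
    if (length(keep) == 0) next
    gs <- runs$gstart[keep] + (a[keep] - runs$uoff[keep])
    res[[i]] <- data.frame(
      rs = s$rs + (a[keep] - s$us), re = s$rs + (b[keep] - s$us),
      chrom = runs$chrom[keep], gs = gs, ge = gs + (b[keep] - a[keep]),
      strand = strand, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(rs = integer(0), re = integer(0),
                      chrom = character(0), gs = integer(0),
                      ge = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the chaining DAG over match blocks
#'
#' Vertices are MBs (from one read, one chromosome and strand); an edge
#' u -> v exists iff v progresses strictly in both read and genome
#' coordinates (overlap up to `overlap_tol` allowed, trimmed at scoring
#' time) and the genomic gap does not exceed the maximum intron length.
#' Edge weight is the trimmed length of v minus a log-penalised diagonal
#' drift, floored at 1 for reachable vertices.
#'
#' @param mbs data.frame of MBs with columns rs, re, gs, ge.
#' @param T_intron maximum intron length in bp (default 200000).
#' @param lambda diagonal-drift penalty factor (default 1).
#' @param overlap_tol maximum allowed read/genome overlap between chained
#'   MBs (default 10 bp).
#' @return list with elements `mbs` (sorted) and `edges`
#'   (data.frame from, to, w).
#' @export
build_dag <- function(mbs, T_intron = 200000L, lambda = 1,
                      overlap_tol = 10L) {
  mbs <- mbs[order(mbs$rs, mbs$gs), , drop = FALSE]
  rownames(mbs) <- NULL
  n <- nrow(mbs)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  if (n > 1) {
    for (u in seq_len(n - 1)) {
      v <- (u + 1):n
      gap_r <- mbs$rs[v] - mbs$re[u]
      gap_g <- mbs$gs[v] - mbs$ge[u]
      ok <- mbs$rs[v] > mbs$rs[u] & mbs$re[v] > mbs$re[u] &
        mbs$gs[v] > mbs$gs[u] & mbs$ge[v] > mbs$ge[u] &
        gap_r >= -overlap_tol & gap_g >= -overlap_tol & gap_g <= T_intron
      if (!any(ok)) next
      v <- v[ok]; gap_r <- gap_r[ok]; gap_g <- gap_g[ok]
      efflen <- (mbs$re[v] - mbs$rs[v]) + pmin(gap_r, 0) + pmin(gap_g, 0)
      wt <- pmax(1, efflen - lambda * log2(1 + abs(gap_g - gap_r)))
      from <- c(from, rep(u, length(v))); to <- c(to, v); w <- c(w, wt)
    }
  }
  list(mbs = mbs, edges = data.frame(from = from, to = to, w = w),
       T_intron = T_intron)
}

#' Chain match blocks by sparse dynamic programming
#'
#' Returns the maximum-weight co-linear path through the DAG as the primary
#' alignment skeleton, plus every additional path ending at a vertex whose
#' chain score is within `epsilon` of the best and whose genomic span does
#' not overlap an already accepted skeleton (up to `max_skeletons`). Path
#' score is the length of the first MB plus the sum of edge weights. Ties
#' are broken toward the leftmost genome coordinate.
#'
#' @param dag as returned by [build_dag()].
#' @param epsilon relative score threshold for reporting secondary
#'   skeletons (default 0.05).
#' @param max_skeletons maximum number of skeletons returned (default 5).
#' @return list of skeletons; each is a list with `mbs` (data.frame) and
#'   `score`.
#' @export
sdp_chain <- function(dag, epsilon = 0.05, max_skeletons = 5L) {
  mbs <- dag$mbs
  n <- nrow(mbs)
  if (n == 0) return(list())
  score <- mbs$re - mbs$rs          # chain starting here: vertex weight
  back <- rep(NA_integer_, n)
  e <- dag$edges
  if (nrow(e) > 0) {
    e <- e[order(e$to, e$from), ]
    for (i in seq_len(nrow(e))) {
      cand <- score[e$from[i]] + e$w[i]
      v <- e$to[i]
      if (cand > score[v] ||
          (cand == score[v] && !is.na(back[v]) &&
           mbs$gs[e$from[i]] < mbs$gs[back[v]])) {
        score[v] <- cand
        back[v] <- e$from[i]
      }
    }
  }
  trace <- function(v) {
    path <- integer(0)
    while (!is.na(v)) { path <- c(v, path); v <- back[v] }
    path
  }
  ord <- order(-score, mbs$gs)
  best <- score[ord[1]]
  skeletons <- list()
  spans <- data.frame(chrom = character(0), gs = integer(0), ge = integer(0),
                      stringsAsFactors = FALSE)
  for (v in ord) {
    if (score[v] < (1 - epsilon) * best) break
    if (length(skeletons) >= max_skeletons) break
    path <- trace(v)
    pmbs <- mbs[path, , drop = FALSE]
    gs <- min(pmbs$gs); ge <- max(pmbs$ge)
    chrom <- pmbs$chrom[1]
    if (nrow(spans) > 0 &&
        any(spans$chrom == chrom & spans$gs < ge & spans$ge > gs)) next
    spans <- rbind(spans, data.frame(chrom = chrom, gs = gs, ge = ge,
                                     stringsAsFactors = FALSE))
    rownames(pmbs) <- NULL
    skeletons[[length(skeletons) + 1]] <- list(mbs = pmbs, score = score[v])
  }
  skeletons
}

#' Compute alignment skeletons for one read (both strands)
#'
#' Seeds the read and its reverse complement against the forward-strand
#' index, builds per-(chromosome, strand) chaining DAGs and pools the
#' resulting skeletons: the best-scoring skeleton plus all others within
#' `epsilon` of it (up to `max_skeletons`). For minus-strand skeletons the
#' MB read coordinates refer to the reverse-complemented read, which is
#' also the query used in the second pass.
#'
#' @param index an `rdbg_index`.
#' @param seq read sequence.
#' @param m seed stride (default 5).
#' @param T_intron maximum intron length (default 200000).
#' @param epsilon secondary-skeleton score threshold (default 0.05).
#' @param max_skeletons cap on reported skeletons (default 5).
#' @param slack SU-MEM merge slack (default 2).
#' @param max_mbs cap on chaining problem size; the longest blocks are kept
#'   when exceeded (default 400).
#' @param rescue retry seeding at stride 1 when the strided pass finds no
#'   skeleton at all (default TRUE).
#' @return list of skeletons, each a list with `mbs`, `score`, `chrom`,
#'   `strand`.
#' @export
read_skeletons <- function(index, seq, m = 5L, T_intron = 200000L,
                           epsilon = 0.05, max_skeletons = 5L, slack = 2L,
                           max_mbs = 400L, rescue = TRUE) {
  sk <- .read_skeletons_stride(index, seq, m, T_intron, epsilon,
                               max_skeletons, slack, max_mbs)
  ## error-dense reads miss most strided seed windows even though exact
  ## l-mers exist; when the best skeleton anchors too little of the read,
  ## retry with every offset and keep the better result
  if (rescue && m > 1L) {
    cov <- if (length(sk) == 0) 0
           else sum(sk[[1]]$mbs$re - sk[[1]]$mbs$rs) / nchar(seq)
    if (cov < 0.5) {
      sk2 <- .read_skeletons_stride(index, seq, 1L, T_intron, epsilon,
                                    max_skeletons, slack, max_mbs)
      if (length(sk2) > 0 &&
          (length(sk) == 0 || sk2[[1]]$score > sk[[1]]$score))
        sk <- sk2
    }
  }
  sk
}

.read_skeletons_stride <- function(index, seq, m, T_intron, epsilon,
                                   max_skeletons, slack, max_mbs) {
  all_sk <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    umems <- find_umems(index, s, m = m)
    if (nrow(umems) == 0) next
    sumems <- merge_sumems(umems, slack = slack)
    mbs <- project_to_mbs(index, sumems, strand = strand)
    if (nrow(mbs) == 0) next
    for (chrom in unique(mbs$chrom)) {
      grp <- mbs[mbs$chrom == chrom, , drop = FALSE]
      if (nrow(grp) > max_mbs)
        grp <- grp[order(grp$rs - grp$re)[seq_len(max_mbs)], , drop = FALSE]
      dag <- build_dag(grp, T_intron = T_intron)
      sks <- sdp_chain(dag, epsilon = epsilon,
                       max_skeletons = max_skeletons)
      for (sk in sks) {
        sk$chrom <- chrom
        sk$strand <- strand
        all_sk[[length(all_sk) + 1]] <- sk
      }
    }
  }
  if (length(all_sk) == 0) return(list())
  scores <- vapply(all_sk, `[[`, numeric(1), "score")
  best <- max(scores)
  keep <- which(scores >= (1 - epsilon) * best)
  keep <- keep[order(-scores[keep])]
  if (length(keep) > max_skeletons) keep <- keep[seq_len(max_skeletons)]
  all_sk[keep]
}
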