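## Second-pass (refined) alignment: each read's skeleton anchors a corridor
## of inferred exons; read parts between neighboring MBs vote for "spanning
## exons" via short s-mer matches; the spanning exons are stitched into a
## local spliced reference sequence (LSRS) against which the whole read is
## aligned semi-globally; large deletions trigger LSRS excision and
## realignment; finally the LSRS alignment is lifted to a spliced genome
## CIGAR with N operations at segment junctions.

#' Alignment scoring parameters
#'
#' @param match match reward (> 0), default 2.
#' @param mismatch mismatch penalty (<= 0), default -4.
#' @param gap_open gap opening penalty (<= 0), default -4; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param gap_extend gap extension penalty (<= 0), default -2.
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -4L, gap_open = -4L,
                          gap_extend = -2L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' Split a read into parts between neighboring skeleton MBs
#'
#' One part per consecutive MB pair, plus a head part before the first MB
#' and a tail part after the last; empty parts are dropped. Anchor MB row
#' indices are attached (NA at read ends).
#'
#' @param read_len read length.
#' @param skeleton a skeleton (list with `mbs`).
#' @return data.frame with columns rs, re, left_mb, right_mb.
#' @export
split_read <- function(read_len, skeleton) {
  mb <- skeleton$mbs
  n <- nrow(mb)
  starts <- c(0L, mb$re)
  ends <- c(mb$rs, read_len)
  left <- c(NA_integer_, seq_len(n))
  right <- c(seq_len(n), NA_integer_)
  keep <- ends > starts
  data.frame(rs = starts[keep], re = ends[keep],
             left_mb = left[keep], right_mb = right[keep])
}

#' Find the inferred exons hit by a read part
#'
#' An exon in the genomic corridor between (or flanking) the part's anchor
#' MBs is "hit" when at least one exact s-mer of the part occurs in its
#' sequence. Exons overlapping the anchor MBs themselves are always
#' included by the caller.
#'
#' @param part_seq read-part sequence (may be empty).
#' @param exons data.frame of exon regions (chrom, start, end).
#' @param reference named character vector of chromosome sequences.
#' @param corridor c(lo, hi) genomic corridor (0-based half-open).
#' @param chrom chromosome of the corridor.
#' @param s short seed length (default 8).
#' @return data.frame of hit exons, sorted genomically.
#' @export
find_hit_exons <- function(part_seq, exons, reference, corridor, chrom,
                           s = 8L) {
  cand <- exons[exons$chrom == chrom & exons$end > corridor[1] &
                  exons$start < corridor[2], , drop = FALSE]
  if (nrow(cand) == 0 || is.na(part_seq) || nchar(part_seq) < s)
    return(cand[0, , drop = FALSE])
  hit <- vapply(seq_len(nrow(cand)), function(i) {
    ## scan with a 10 bp flank: inferred boundaries can be a few bases
    ## short and a part's only clean s-mer may straddle the true boundary
    eseq <- substr(reference[[chrom]], max(1L, cand$start[i] - 9L),
                   cand$end[i] + 10L)
    diags <- cpp_smer_diagonals(part_seq, eseq, as.integer(s))
    if (length(diags) == 0) return(FALSE)
    ## a single s-mer suffices for short exons/parts (they cannot offer two
    ## windows); large exons hit by a long part must show either two hits
    ## on a consistent diagonal or simply two hits, to damp chance matches
    if (nchar(eseq) < 64L || nchar(part_seq) < 2L * s) return(TRUE)
    length(diags) >= 2L
  }, logical(1))
  out <- cand[hit, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Compose a local spliced reference sequence
#'
#' Overlapping or abutting input intervals are merged first; the LSRS is the
#' concatenation of the genomic substrings in genomic order, with a segment
#' map tiling the LSRS exactly.
#'
#' @param segments data.frame with columns start, end (0-based half-open).
#' @param reference named character vector of chromosome sequences.
#' @param chrom chromosome.
#' @return object of class `lsrs`: list(seq, map, chrom) where map has
#'   columns ls, le (LSRS interval) and gs, ge (genome interval).
#' @export
compose_lsrs <- function(segments, reference, chrom) {
  if (nrow(segments) == 0)
    stop("cannot compose LSRS from an empty exon set")
  m <- merge_intervals(segments$start, segments$end)
  widths <- m$end - m$start
  le <- cumsum(widths)
  ls <- le - widths
  seqs <- substring(reference[[chrom]], m$start + 1L, m$end)
  structure(list(
    seq = paste(seqs, collapse = ""),
    map = data.frame(ls = ls, le = le, gs = m$start, ge = m$end),
    chrom = chrom), class = "lsrs")
}

#' Semi-global alignment of a query against a reference window
#'
#' Affine-gap dynamic programming; the query is aligned end-to-end while
#' both reference ends are free of gap penalty. Returns the optimal score,
#' the CIGAR over the reference (M/I/D) and the covered reference window.
#'
#' @param query query sequence.
#' @param ref reference sequence.
#' @param scoring an [align_scoring()] object.
#' @return list(score, cigar, ref_start, ref_end).
#' @export
semiglobal_align <- function(query, ref, scoring = align_scoring()) {
  cpp_semiglobal(query, ref, scoring$match, scoring$mismatch,
                 scoring$gap_open, scoring$gap_extend)
}

#' Excise large deletions from the LSRS and realign
#'
#' Every deletion run of at least `D_min` bp in the LSRS-space CIGAR is
#' removed from the LSRS (splitting the segment map, which creates a
#' junction), the query is realigned against the updated LSRS, and the
#' higher-scoring result is kept. Iterates until no deletion >= `D_min`
#' remains or `max_rounds` rounds have run.
#'
#' @param aln first-round alignment from [semiglobal_align()].
#' @param lsrs the `lsrs` the alignment was computed against.
#' @param query the query sequence.
#' @param scoring an [align_scoring()] object.
#' @param D_min large-deletion threshold in bp (default 30).
#' @param max_rounds maximum excision rounds (default 3).
#' @return list(aln, lsrs) with the kept alignment and its LSRS.
#' @export
realign_large_deletions <- function(aln, lsrs, query,
                                    scoring = align_scoring(),
                                    D_min = 30L, max_rounds = 3L) {
  for (round in seq_len(max_rounds)) {
    co <- cigar_ops(aln$cigar)
    ref_pos <- aln$ref_start +
      c(0, cumsum(ifelse(co$op %in% c("M", "D", "N"), co$len, 0)))[
        seq_len(nrow(co))]
    big <- which(co$op == "D" & co$len >= D_min)
    if (length(big) == 0) break
    cut_s <- ref_pos[big]
    cut_e <- ref_pos[big] + co$len[big]
    ## remove the cut intervals from the segment map, then recompose
    map <- lsrs$map
    gsegs <- list()
    for (i in seq_len(nrow(map))) {
      cur <- data.frame(start = map$ls[i], end = map$le[i])
      for (j in seq_along(cut_s)) {
        nxt <- list()
        for (r in seq_len(nrow(cur))) {
          a <- cur$start[r]; b <- cur$end[r]
          if (cut_e[j] <= a || cut_s[j] >= b) {
            nxt[[length(nxt) + 1]] <- c(a, b)
          } else {
            if (cut_s[j] > a) nxt[[length(nxt) + 1]] <- c(a, cut_s[j])
            if (cut_e[j] < b) nxt[[length(nxt) + 1]] <- c(cut_e[j], b)
          }
        }
        cur <- if (length(nxt))
          data.frame(start = vapply(nxt, `[`, numeric(1), 1),
                     end = vapply(nxt, `[`, numeric(1), 2))
        else cur[0, , drop = FALSE]
      }
      if (nrow(cur))
        gsegs[[length(gsegs) + 1]] <-
          data.frame(start = map$gs[i] + (cur$start - map$ls[i]),
                     end = map$gs[i] + (cur$end - map$ls[i]))
    }
    gsegs <- do.call(rbind, gsegs)
    if (is.null(gsegs) || nrow(gsegs) == 0) break
    widths <- gsegs$end - gsegs$start
    le <- cumsum(widths); ls <- le - widths
    ## carve the new LSRS sequence out of the old one via the old map
    old <- lsrs$map
    seq_piece <- character(nrow(gsegs))
    for (r in seq_len(nrow(gsegs))) {
      seg <- which(old$gs <= gsegs$start[r] & old$ge >= gsegs$end[r])[1]
      a <- old$ls[seg] + (gsegs$start[r] - old$gs[seg])
      b <- a + widths[r]
      seq_piece[r] <- substr(lsrs$seq, a + 1L, b)
    }
    new_lsrs <- structure(list(
      seq = paste(seq_piece, collapse = ""),
      map = data.frame(ls = ls, le = le, gs = gsegs$start, ge = gsegs$end),
      chrom = lsrs$chrom), class = "lsrs")
    new_aln <- semiglobal_align(query, new_lsrs$seq, scoring)
    ## a deletion this large becomes an intron either way (excision creates
    ## a junction; an unexcised D next to one is absorbed at lift time), so
    ## compare scores with the excised runs' gap penalties refunded --
    ## otherwise excision always "wins" and can eat true exon sequence when
    ## the first-round tail was misaligned
    refund <- sum(-(scoring$gap_open + scoring$gap_extend * co$len[big]))
    if (new_aln$score >= aln$score + refund - 2L) {
      aln <- new_aln
      lsrs <- new_lsrs
    } else break
  }
  list(aln = aln, lsrs = lsrs)
}

#' Lift an LSRS-space alignment to a spliced genome alignment
#'
#' M/I/D operations are mapped through the segment map; each segment
#' junction crossed by the alignment introduces an N operation whose length
#' is the genomic gap. Deletion runs adjacent to an N operation are
#' absorbed into the intron (they represent reference bases on the far side
#' of a junction that the read does not support).
#'
#' @param aln alignment from [semiglobal_align()] against the LSRS.
#' @param lsrs the `lsrs`.
#' @param min_exon_m minimum aligned (M) bases for an exon segment to
#'   survive micro-exon cleanup (default 8; see Details).
#' @return list(chrom, pos, cigar, score): a spliced genome alignment
#'   (0-based `pos`).
#' @export
lift_to_genome <- function(aln, lsrs, min_exon_m = 8L) {
  co <- cigar_ops(aln$cigar)
  map <- lsrs$map
  lp <- aln$ref_start              # current LSRS position
  seg <- findInterval(lp, map$ls)  # current segment index
  if (seg < 1 || seg > nrow(map)) stop("CIGAR overruns segment map")
  pos <- map$gs[seg] + (lp - map$ls[seg])
  out_len <- integer(0); out_op <- character(0)
  emit <- function(len, op) {
    out_len <<- c(out_len, len); out_op <<- c(out_op, op)
  }
  for (i in seq_len(nrow(co))) {
    len <- co$len[i]; op <- co$op[i]
    if (op == "I") { emit(len, "I"); next }
    if (!op %in% c("M", "D")) stop("unexpected op in LSRS CIGAR: ", op)
    while (len > 0) {
      room <- map$le[seg] - lp
      if (room == 0) {
        if (seg == nrow(map)) stop("CIGAR overruns segment map")
        emit(map$gs[seg + 1] - map$ge[seg], "N")
        seg <- seg + 1
        lp <- map$ls[seg]
        next
      }
      take <- min(len, room)
      emit(take, op)
      lp <- lp + take
      len <- len - take
    }
  }
  ## absorb D runs adjacent to N into the intron (reference bases across a
  ## junction that the read does not support belong to the intron, not to a
  ## phantom exon)
  repeat {
    nxt <- c(out_op[-1], "")
    prv <- c("", out_op[-length(out_op)])
    dn <- which(out_op == "D" & (nxt == "N" | prv == "N"))
    if (length(dn) == 0) break
    i <- dn[1]
    j <- if (i < length(out_op) && out_op[i + 1] == "N") i + 1L else i - 1L
    out_len[j] <- out_len[j] + out_len[i]
    out_len <- out_len[-i]; out_op <- out_op[-i]
  }
  ## leading/trailing N (possible after absorption at the edges) is clipped
  ## into the position / dropped
  while (length(out_op) && out_op[1] == "N") {
    pos <- pos + out_len[1]
    out_len <- out_len[-1]; out_op <- out_op[-1]
  }
  while (length(out_op) && out_op[length(out_op)] == "N") {
    out_len <- out_len[-length(out_len)]; out_op <- out_op[-length(out_op)]
  }
  cleaned <- clean_micro_exons(pos, out_len, out_op, min_exon_m)
  list(chrom = lsrs$chrom, pos = cleaned$pos,
       cigar = cigar_string(cleaned$len, cleaned$op), score = aln$score)
}

## Exon segments of a spliced CIGAR carrying fewer than `min_exon_m` aligned
## (M) bases are spurious: a handful of noisy read bases chance-matching an
## LSRS segment across a junction. Internal micro-segments are absorbed into
## the surrounding intron (query bases become I); terminal ones become soft
## clips. Runs until stable; at least one segment always survives.
clean_micro_exons <- function(pos, len, op, min_exon_m) {
  repeat {
    ## (re)absorb D runs adjacent to N and strip edge Ns
    repeat {
      nxt <- c(op[-1], ""); prv <- c("", op[-length(op)])
      dn <- which(op == "D" & (nxt == "N" | prv == "N"))
      if (length(dn) == 0) break
      i <- dn[1]
      j <- if (i < length(op) && op[i + 1] == "N") i + 1L else i - 1L
      len[j] <- len[j] + len[i]
      len <- len[-i]; op <- op[-i]
    }
    ## a 1-3 bp chance-matched island between a sizeable D run and an N
    ## blocks absorption: turn the island into an insertion and retry
    island <- FALSE
    for (i in which(op == "N")) {
      if (i >= 3 && op[i - 1] == "M" && len[i - 1] <= 3L &&
          op[i - 2] == "D" && len[i - 2] >= 5L) {
        op[i - 1] <- "I"; island <- TRUE; break
      }
      if (i + 2 <= length(op) && op[i + 1] == "M" && len[i + 1] <= 3L &&
          op[i + 2] == "D" && len[i + 2] >= 5L) {
        op[i + 1] <- "I"; island <- TRUE; break
      }
    }
    if (island) next
    while (length(op) && op[1] == "N") {
      pos <- pos + len[1]; len <- len[-1]; op <- op[-1]
    }
    while (length(op) && op[length(op)] == "N") {
      len <- len[-length(len)]; op <- op[-length(op)]
    }
    nidx <- which(op == "N")
    if (length(nidx) == 0) break
    bounds <- c(0L, nidx, length(op) + 1L)
    seg_m <- integer(length(nidx) + 1L)
    seg_q <- integer(length(nidx) + 1L)
    seg_r <- integer(length(nidx) + 1L)
    for (s in seq_along(seg_m)) {
      span <- (bounds[s] + 1L):(bounds[s + 1L] - 1L)
      seg_m[s] <- sum(len[span][op[span] == "M"])
      seg_q[s] <- sum(len[span][op[span] %in% c("M", "I", "S")])
      seg_r[s] <- sum(len[span][op[span] %in% c("M", "D")])
    }
    victim <- which(seg_m < min_exon_m)
    if (length(victim) == 0) break
    s <- victim[which.min(seg_m[victim])]
    span <- (bounds[s] + 1L):(bounds[s + 1L] - 1L)
    if (s == 1L) {
      ## leading segment -> soft clip; following N collapses into pos
      newlen <- c(if (seg_q[s] > 0) seg_q[s], len[-c(span, bounds[s + 1L])])
      newop <- c(if (seg_q[s] > 0) "S", op[-c(span, bounds[s + 1L])])
      pos <- pos + seg_r[s] + len[bounds[s + 1L]]
      len <- newlen; op <- newop
    } else if (s == length(seg_m)) {
      drop <- c(bounds[s], span)
      tail_s <- if (seg_q[s] > 0) seg_q[s]
      len <- c(len[-drop], tail_s)
      op <- c(op[-drop], if (seg_q[s] > 0) "S")
    } else {
      ## internal: query bases become I, reference span joins the intron
      repl_len <- c(if (seg_q[s] > 0) seg_q[s],
                    len[bounds[s]] + seg_r[s] + len[bounds[s + 1L]])
      repl_op <- c(if (seg_q[s] > 0) "I", "N")
      keep_pre <- seq_len(bounds[s] - 1L)
      keep_post <- if (bounds[s + 1L] < length(op))
        (bounds[s + 1L] + 1L):length(op) else integer(0)
      len <- c(len[keep_pre], repl_len, len[keep_post])
      op <- c(op[keep_pre], repl_op, op[keep_post])
    }
  }
  list(pos = pos, len = len, op = op)
}

#' Polish splice junctions of a lifted alignment
#'
#' For each N operation flanked by M runs, the junction is slid within a
#' small window to the offset that maximises base matches of the
#' surrounding query bases plus a canonical splice-signal bonus (GT..AG on
#' either strand orientation); sliding moves query bases between the two
#' flanking exons while keeping the intron length fixed. Junctions whose
#' neighborhoods degenerated into small indel/match debris (non-M ops next
#' to the N) are instead rebuilt outright: the outer genome anchors stay
#' fixed and every pure-M split of the neighborhood's query bases between
#' the two exons is rescored, keeping the rebuild only when it outscores
#' the current configuration under the same local metric. Both mechanisms
#' recover exact junctions when the inferred exon boundaries that shaped
#' the LSRS were a few bases off.
#'
#' @param pos 0-based alignment start.
#' @param cigar spliced genome CIGAR.
#' @param query the aligned query sequence (reference orientation).
#' @param refseq the chromosome sequence.
#' @param w query bases examined on each side of a junction (default 16).
#' @param bonus score bonus per matching canonical splice dinucleotide
#'   (default 3; base matches score 2).
#' @param scoring an [align_scoring()] object for the debris rescoring.
#' @return list(pos, cigar) with polished junctions.
#' @export
polish_junctions <- function(pos, cigar, query, refseq, w = 16L,
                             bonus = 3L, scoring = align_scoring()) {
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  rstr <- function(a, b) substr(refseq, a + 1L, b)  # 0-based half-open
  rchar <- function(a, n) {
    if (n <= 0) return(character(0))
    strsplit(substr(refseq, a + 1L, a + n), "", fixed = TRUE)[[1]]
  }
  sig_bonus <- function(Le, Rs) {
    don <- rstr(Le, Le + 2L)
    acc <- rstr(Rs - 2L, Rs)
    max((don == "GT") + (acc == "AG"), (don == "CT") + (acc == "AC")) * bonus
  }
  ## small insertion runs stuck against a junction are query bases the LSRS
  ## had no room for (an inward-short exon segment): give them intron
  ## reference to align to and let the slide find the right split
  co <- cigar_ops(cigar)
  len <- co$len; op <- co$op
  repeat {
    ni <- which(op == "N")
    conv <- FALSE
    for (i in ni) {
      if (i >= 2 && op[i - 1] == "I" && len[i - 1] <= 12L &&
          len[i - 1] < len[i]) {
        len[i] <- len[i] - len[i - 1]
        op[i - 1] <- "M"
        conv <- TRUE
        break
      }
      if (i < length(op) && op[i + 1] == "I" && len[i + 1] <= 12L &&
          len[i + 1] < len[i]) {
        len[i] <- len[i] - len[i + 1]
        op[i + 1] <- "M"
        conv <- TRUE
        break
      }
    }
    if (!conv) break
  }
  cigar <- cigar_string(len, op)

  jn <- 0L
  repeat {
    co <- cigar_ops(cigar)
    len <- co$len; op <- co$op
    nidx <- which(op == "N")
    jn <- jn + 1L
    if (jn > length(nidx)) break
    i <- nidx[jn]
    if (i < 2 || i >= length(op)) next
    qcons <- op %in% c("M", "I", "S")
    rcons <- op %in% c("M", "D", "N")
    qbefore <- c(0L, cumsum(len * qcons))
    rbefore <- pos + c(0L, cumsum(len * rcons))

    if (op[i - 1] == "M" && op[i + 1] == "M" &&
        len[i - 1] >= 3L && len[i + 1] >= 3L) {
      ## slide: junction moves, intron length fixed
      qe <- qbefore[i]
      L <- rbefore[i]
      R <- rbefore[i + 1]
      ww <- min(w, len[i - 1] - 1L, len[i + 1] - 1L)
      if (ww < 2L) next
      smax <- min(ww - 1L, 12L)
      lgen <- strsplit(rstr(L - ww, L + smax), "", fixed = TRUE)[[1]]
      rgen <- strsplit(rstr(R - smax, R + ww), "", fixed = TRUE)[[1]]
      qwin <- qc[(qe - ww + 1L):(qe + ww)]
      best_s <- 0L; best_score <- -Inf
      for (s in -smax:smax) {
        nl <- ww + s
        ml <- if (nl > 0) sum(qwin[seq_len(nl)] == lgen[seq_len(nl)]) else 0L
        mr <- if (nl < 2 * ww)
          sum(qwin[(nl + 1L):(2L * ww)] ==
                rgen[(smax + s + 1L):(smax + s + 2L * ww - nl)]) else 0L
        sc <- 2L * (ml + mr) + sig_bonus(L + s, R + s)
        if (sc > best_score || (sc == best_score && abs(s) < abs(best_s))) {
          best_score <- sc; best_s <- s
        }
      }
      if (best_s != 0L) {
        len[i - 1] <- len[i - 1] + best_s
        len[i + 1] <- len[i + 1] - best_s
        cigar <- cigar_string(len, op)
      }
      next
    }

  }
  list(pos = pos, cigar = cigar)
}

#' Select the primary alignment and assign MAPQ
#'
#' The highest-scoring candidate becomes primary (ties broken toward the
#' leftmost chromosome/position); the rest are flagged secondary.
#' MAPQ = min(60, floor(40 (s1 - s2) / s1) + 20) with s2 = 0 when unique,
#' and MAPQ = 0 on a score tie.
#'
#' @param cands data.frame of candidate alignments with columns score,
#'   chrom, pos (one row per skeleton per strand).
#' @return the same data.frame ordered primary-first, with `is_primary` and
#'   `mapq` columns added; zero rows in yields zero rows out (the caller
#'   emits an unmapped record).
#' @export
select_primary <- function(cands) {
  if (nrow(cands) == 0) {
    cands$is_primary <- logical(0)
    cands$mapq <- integer(0)
    return(cands)
  }
  o <- order(-cands$score, cands$chrom, cands$pos)
  cands <- cands[o, , drop = FALSE]
  rownames(cands) <- NULL
  s1 <- cands$score[1]
  cands$is_primary <- c(TRUE, rep(FALSE, nrow(cands) - 1))
  if (nrow(cands) == 1) {
    mapq <- 60L
  } else {
    s2 <- cands$score[2]
    mapq <- if (s1 == s2) 0L
            else min(60L, as.integer(floor(40 * (s1 - s2) / s1)) + 20L)
  }
  cands$mapq <- c(mapq, rep(0L, nrow(cands) - 1))
  cands
}

#' Refined (second-pass) alignment of one read
#'
#' For each first-pass skeleton: read parts vote for spanning exons inside
#' the skeleton's genomic corridor, the spanning exons plus the anchor MB
#' footprints are stitched into an LSRS, and the whole read (oriented by
#' the skeleton strand) is aligned semi-globally against it, with
#' large-deletion excision and lifting to a spliced genome CIGAR. With
#' `exons = NULL` (single-pass ablation) the LSRS is built from the anchor
#' MB footprints alone.
#'
#' @param seq read sequence (original orientation).
#' @param skeletons skeleton list from [read_skeletons()].
#' @param exons inferred exon regions (or NULL for single-pass mode).
#' @param reference named character vector of chromosome sequences.
#' @param scoring an [align_scoring()] object.
#' @param s short seed length for exon hitting (default 8).
#' @param D_min large-deletion threshold (default 30).
#' @param corridor_pad corridor extension beyond the anchor span (default
#'   20000 bp; read parts beyond the outermost anchors may span several
#'   introns).
#' @param min_exon_m micro-exon cleanup threshold (default 8).
#' @return data.frame of candidate alignments (score, chrom, pos, strand,
#'   cigar), one row per skeleton, ordered by [select_primary()].
#' @export
align_read <- function(seq, skeletons, exons, reference,
                       scoring = align_scoring(), s = 8L, D_min = 30L,
                       corridor_pad = 20000L, min_exon_m = 8L) {
  cands <- list()
  for (sk in skeletons) {
    query <- if (sk$strand == "+") seq else revcomp(seq)
    mb <- sk$mbs
    chrom <- sk$chrom
    corridor <- c(max(0L, min(mb$gs) - corridor_pad),
                  min(nchar(reference[[chrom]]), max(mb$ge) + corridor_pad))
    if (!is.null(exons) && nrow(exons) > 0) {
      ## anchor-overlapping exons are always spanning exons
      anchor_hits <- exons[exons$chrom == chrom &
                             Reduce(`|`, lapply(seq_len(nrow(mb)), function(i)
                               exons$end > mb$gs[i] & exons$start < mb$ge[i])),
                           , drop = FALSE]
      segs <- anchor_hits[, c("start", "end")]
      parts <- split_read(nchar(query), sk)
      for (p in seq_len(nrow(parts))) {
        lo <- if (is.na(parts$left_mb[p])) corridor[1]
              else mb$ge[parts$left_mb[p]] - 50L
        hi <- if (is.na(parts$right_mb[p])) corridor[2]
              else mb$gs[parts$right_mb[p]] + 50L
        pseq <- substr(query, parts$rs[p] + 1L, parts$re[p])
        hits <- find_hit_exons(pseq, exons, reference, c(lo, hi), chrom,
                               s = s)
        if (nrow(hits))
          segs <- rbind(segs, hits[, c("start", "end")])
      }
      ## anchor MB footprints back up the spanning exons where inference
      ## found nothing, but must not override refined exon boundaries:
      ## only residual pieces >= 4 bp are added (1-3 bp pieces are chance
      ## MEM overhangs across splice junctions)
      if (nrow(segs) > 0) {
        resid <- IRanges::setdiff(
          IRanges::reduce(IRanges::IRanges(mb$gs + 1L, mb$ge)),
          IRanges::reduce(IRanges::IRanges(segs$start + 1L, segs$end)))
        resid <- resid[IRanges::width(resid) >= 4L]
        if (length(resid))
          segs <- rbind(segs, data.frame(start = IRanges::start(resid) - 1L,
                                         end = IRanges::end(resid)))
      } else {
        segs <- data.frame(start = mb$gs, end = mb$ge)
      }
    } else {
      segs <- data.frame(start = mb$gs, end = mb$ge)
    }
    ## terminal segments get a small outward flank: semi-global reference
    ## ends are free, and the flank repairs terminal exon boundaries that
    ## splice refinement nudged inward
    msegs <- merge_intervals(segs$start, segs$end)
    msegs$start[1] <- max(0L, msegs$start[1] - 20L)
    msegs$end[nrow(msegs)] <- min(nchar(reference[[chrom]]),
                                  msegs$end[nrow(msegs)] + 20L)
    lsrs <- compose_lsrs(msegs, reference, chrom)
    if (as.double(nchar(query) + 1) * (nchar(lsrs$seq) + 1) > 3e8) {
      ## corridor blew up; retreat to the anchor footprints
      lsrs <- compose_lsrs(data.frame(start = mb$gs, end = mb$ge),
                           reference, chrom)
    }
    aln <- semiglobal_align(query, lsrs$seq, scoring)
    res <- realign_large_deletions(aln, lsrs, query, scoring, D_min = D_min)
    g <- lift_to_genome(res$aln, res$lsrs, min_exon_m = min_exon_m)
    pol <- polish_junctions(g$pos, g$cigar, query, reference[[chrom]])
    cands[[length(cands) + 1]] <-
      data.frame(score = g$score, chrom = g$chrom, pos = pol$pos,
                 strand = sk$strand, cigar = pol$cigar,
                 stringsAsFactors = FALSE)
  }
  cands <- if (length(cands)) do.call(rbind, cands)
           else data.frame(score = numeric(0), chrom = character(0),
                           pos = integer(0), strand = character(0),
                           cigar = character(0), stringsAsFactors = FALSE)
  select_primary(cands)
}
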