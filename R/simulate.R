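## Synthetic data: multi-exon gene models with alternative isoforms on a
## random genome, spliced transcripts, a two-level (30x/4x) expression
## profile, and error-bearing long reads under four named error models,
## each read carrying exact per-base ground truth.

#' Specification of a synthetic gene model
#'
#' @param n_genes number of genes.
#' @param exon_count integer range c(min, max) of exons per gene.
#' @param exon_len bp range of exon lengths.
#' @param intron_len bp range of intron lengths.
#' @param intergenic bp range of intergenic gaps.
#' @param multi_isoform_frac fraction of genes receiving a second,
#'   exon-skipping isoform.
#' @param short_exon_rate fraction of (>= 3 exon) genes in which one
#'   internal exon is forced short (< 31 bp).
#' @param antisense_overlap also emit at least one minus-strand gene nested
#'   inside another gene's intron (overlapping coordinates, opposite
#'   strands).
#' @param chrom_budget optional maximum chromosome length; the generator
#'   errors if the model cannot fit.
#' @return list of class `gene_model_spec`.
#' @export
gene_model_spec <- function(n_genes = 20L, exon_count = c(2L, 10L),
                            exon_len = c(20L, 300L),
                            intron_len = c(200L, 5000L),
                            intergenic = c(500L, 2000L),
                            multi_isoform_frac = 0.5,
                            short_exon_rate = 0.2,
                            antisense_overlap = FALSE,
                            chrom_budget = NULL) {
  stopifnot(n_genes >= 1, exon_count[1] >= 1, exon_len[1] > 0,
            intron_len[1] > 0, intergenic[1] >= 0,
            multi_isoform_frac >= 0, multi_isoform_frac <= 1,
            short_exon_rate >= 0, short_exon_rate <= 1)
  structure(list(n_genes = n_genes, exon_count = exon_count,
                 exon_len = exon_len, intron_len = intron_len,
                 intergenic = intergenic,
                 multi_isoform_frac = multi_isoform_frac,
                 short_exon_rate = short_exon_rate,
                 antisense_overlap = antisense_overlap,
                 chrom_budget = chrom_budget),
            class = "gene_model_spec")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome and annotation
#'
#' Genes are laid out left to right on one chromosome, non-overlapping and
#' on the forward strand (optionally plus nested antisense genes); every
#' intron carries canonical GT...AG boundaries. Genes hit by the
#' multi-isoform fraction get a second isoform skipping one exon. The
#' output is deterministic under the seed.
#'
#' @param spec a [gene_model_spec()].
#' @param seed RNG seed.
#' @return list(reference, annotation).
#' @export
generate_genome <- function(spec, seed = 1L) {
  with_seed(seed, {
    runif_int <- function(r)
      as.integer(r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L)
    chrom_parts <- character(0)
    cursor <- 0L
    exon_rows <- list()
    for (g in seq_len(spec$n_genes)) {
      gap <- runif_int(spec$intergenic)
      chrom_parts <- c(chrom_parts, rand_seq(gap))
      cursor <- cursor + gap
      ne <- runif_int(spec$exon_count)
      elens <- vapply(seq_len(ne), function(i) runif_int(spec$exon_len),
                      integer(1))
      if (ne >= 3 && runif(1) < spec$short_exon_rate)
        elens[sample(2:(ne - 1), 1L)] <- sample(20:30, 1L)
      ilens <- if (ne > 1)
        vapply(seq_len(ne - 1), function(i) runif_int(spec$intron_len),
               integer(1)) else integer(0)
      gene_id <- sprintf("g%03d", g)
      estart <- integer(ne); eend <- integer(ne)
      for (i in seq_len(ne)) {
        estart[i] <- cursor
        chrom_parts <- c(chrom_parts, rand_seq(elens[i]))
        cursor <- cursor + elens[i]
        eend[i] <- cursor
        if (i < ne) {
          intron <- rand_seq(ilens[i])
          substr(intron, 1, 2) <- "GT"
          substr(intron, ilens[i] - 1L, ilens[i]) <- "AG"
          chrom_parts <- c(chrom_parts, intron)
          cursor <- cursor + ilens[i]
        }
      }
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
        chrom = "chr1", strand = "+", start = estart, end = eend,
        stringsAsFactors = FALSE)
      if (ne >= 2 && runif(1) < spec$multi_isoform_frac) {
        skip <- if (ne >= 3) sample(2:(ne - 1), 1L) else 2L
        keep <- setdiff(seq_len(ne), skip)
        exon_rows[[length(exon_rows) + 1]] <- data.frame(
          gene_id = gene_id, transcript_id = paste0(gene_id, ".t2"),
          chrom = "chr1", strand = "+", start = estart[keep],
          end = eend[keep], stringsAsFactors = FALSE)
      }
    }
    tailgap <- runif_int(spec$intergenic)
    chrom_parts <- c(chrom_parts, rand_seq(tailgap))
    cursor <- cursor + tailgap
    if (!is.null(spec$chrom_budget) && cursor > spec$chrom_budget)
      stop("gene model does not fit the chromosome budget (needs ",
           cursor, " bp)")
    chrom <- paste(chrom_parts, collapse = "")
    exons <- do.call(rbind, exon_rows)
    if (spec$antisense_overlap) {
      ## nest a minus-strand single-exon gene inside the first intron that
      ## can host it
      by_tx <- split(exons, exons$transcript_id)
      placed <- FALSE
      for (tx in by_tx) {
        if (placed || nrow(tx) < 2) next
        introns <- data.frame(start = tx$end[-nrow(tx)], end = tx$start[-1])
        big <- which(introns$end - introns$start >= 600)
        if (length(big)) {
          s <- introns$start[big[1]] + 100L
          exons <- rbind(exons, data.frame(
            gene_id = "gA01", transcript_id = "gA01.t1", chrom = "chr1",
            strand = "-", start = s, end = s + 200L,
            stringsAsFactors = FALSE))
          placed <- TRUE
        }
      }
      if (!placed) stop("no intron can host an antisense gene; widen introns")
    }
    list(reference = c(chr1 = chrom), annotation = gene_annotation(exons))
  })
}

## Strand-aware transcript coordinate map: exons in transcript (5'->3')
## order with cumulative transcript offsets.
tx_map <- function(annotation, transcript_id) {
  ex <- annotation$exons[annotation$exons$transcript_id == transcript_id, ,
                         drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  strand <- ex$strand[1]
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  w <- ex$end - ex$start
  ex$tx_end <- cumsum(w)
  ex$tx_start <- ex$tx_end - w
  ex
}

#' Build transcript sequences from an annotation
#'
#' Per isoform, exon substrings are concatenated 5' to 3'
#' (reverse-complemented for minus-strand genes).
#'
#' @param annotation a `gene_annotation`.
#' @param reference named character vector of chromosome sequences.
#' @return named character vector of transcript sequences.
#' @export
make_transcripts <- function(annotation, reference) {
  ex <- annotation$exons
  txs <- unique(ex$transcript_id)
  out <- vapply(txs, function(tx) {
    e <- ex[ex$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    chrom <- reference[[e$chrom[1]]]
    if (any(e$end > nchar(chrom)) || any(e$start < 0))
      stop("exon out of chromosome bounds for transcript ", tx)
    s <- paste(substring(chrom, e$start + 1L, e$end), collapse = "")
    if (e$strand[1] == "-") revcomp(s) else s
  }, character(1))
  out
}

#' Assign a two-level expression profile to isoforms
#'
#' Per multi-isoform gene exactly one isoform is selected as highly
#' expressed and the others as lowly expressed; all single-isoform genes
#' are highly expressed. Deterministic under the seed.
#'
#' @param annotation a `gene_annotation`.
#' @param seed RNG seed.
#' @param d_high,d_low sequencing depths of the two classes (default 30x
#'   and 4x).
#' @return data.frame with columns transcript_id, gene_id, label, depth.
#' @export
assign_expression <- function(annotation, seed = 1L, d_high = 30,
                              d_low = 4) {
  stopifnot(d_high > 0, d_low > 0)
  ex <- annotation$exons
  tx <- unique(ex[, c("gene_id", "transcript_id")])
  with_seed(seed, {
    out <- do.call(rbind, lapply(split(tx, tx$gene_id), function(g) {
      lab <- rep("lowly", nrow(g))
      lab[if (nrow(g) == 1) 1L else sample(nrow(g), 1L)] <- "highly"
      data.frame(transcript_id = g$transcript_id, gene_id = g$gene_id,
                 label = lab, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out$depth <- ifelse(out$label == "highly", d_high, d_low)
    out
  })
}

#' Named long-read error models
#'
#' Four fixed-parameter models: PacBio reads-of-insert (2% error, 2000 bp
#' mean length), PacBio subreads (15%, 8000 bp), ONT 2D (13%, 7800 bp) and
#' ONT 1D (25%, 7800 bp). PacBio-like models mix errors as 25% substitution
#' / 45% insertion / 30% deletion; ONT-like models as 40/25/35. Read length
#' is gamma-distributed with CV 0.35, truncated at the transcript length.
#'
#' @param name one of "pacbio-roi", "pacbio-subread", "ont-2d", "ont-1d".
#' @return list of class `error_model` with fields name, e (total error
#'   rate), mix (sub/ins/del proportions), mean_len, cv.
#' @export
error_model <- function(name = c("pacbio-roi", "pacbio-subread", "ont-2d",
                                 "ont-1d")) {
  name <- match.arg(name)
  pb_mix <- c(sub = 0.25, ins = 0.45, del = 0.30)
  ont_mix <- c(sub = 0.40, ins = 0.25, del = 0.35)
  par <- switch(name,
    "pacbio-roi" = list(e = 0.02, mix = pb_mix, mean_len = 2000),
    "pacbio-subread" = list(e = 0.15, mix = pb_mix, mean_len = 8000),
    "ont-2d" = list(e = 0.13, mix = ont_mix, mean_len = 7800),
    "ont-1d" = list(e = 0.25, mix = ont_mix, mean_len = 7800))
  structure(c(list(name = name), par, list(cv = 0.35)),
            class = "error_model")
}

## Per-base error injection at event rate q (per source base): substitution
## to a uniformly different base, insertion of a uniform base after the
## current one, or deletion, in the proportions of `mix`.
inject_errors <- function(src, q, mix) {
  n <- nchar(src)
  s <- strsplit(src, "", fixed = TRUE)[[1]]
  u <- runif(n)
  qs <- q * mix[["sub"]]; qi <- q * mix[["ins"]]; qd <- q * mix[["del"]]
  sub <- u < qs
  ins <- u >= qs & u < qs + qi
  del <- u >= qs + qi & u < qs + qi + qd
  bases <- c("A", "C", "G", "T")
  out <- s
  if (any(sub)) {
    code <- match(s[sub], bases) - 1L
    code[is.na(code)] <- 0L
    out[sub] <- bases[(code + sample(1:3, sum(sub), replace = TRUE)) %% 4 + 1]
  }
  ins_base <- character(n)
  ins_base[ins] <- sample(bases, sum(ins), replace = TRUE)
  piece <- out
  piece[del] <- ""
  read <- paste(paste0(piece, ifelse(ins, ins_base, "")), collapse = "")
  list(read = read, keep = !del, ins = ins)
}

## Calibrate the per-base event rate so the realized error rate -- the
## unit-cost edit distance between a simulated read and its source,
## normalised by optimal-alignment columns -- equals the nominal model rate
## e. The analytic first guess q = e / (1 - e * p_ins) accounts for the
## extra alignment columns contributed by insertions; the multiplicative
## Newton refinement on a fixed random-sequence pilot absorbs the
## cancellation of dense error events in the optimal alignment (adjacent
## insertion/deletion pairs realign as substitutions, chance matches), which
## grows with e. The pilot RNG stream is fixed, so the calibrated rate is a
## deterministic function of (e, mix) alone.
.calib_cache <- new.env(parent = emptyenv())

calibrate_event_rate <- function(e, mix, pilot_bases = 60000L) {
  if (e <= 0) return(0)
  key <- paste(e, paste(mix, collapse = ","), pilot_bases)
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  q <- e / (1 - e * mix[["ins"]])
  with_seed(99991L, {
    plen <- 5000L
    srcs <- vapply(seq_len(pilot_bases %/% plen), function(i)
      rand_seq(plen), character(1))
    for (it in 1:3) {
      tot_d <- 0; tot_c <- 0
      for (s in srcs) {
        inj <- inject_errors(s, q, mix)
        band <- max(64L, abs(nchar(inj$read) - plen) + 300L)
        st <- cpp_edit_stats(inj$read, s, band)
        tot_d <- tot_d + st[1]; tot_c <- tot_c + st[2]
      }
      r <- tot_d / tot_c
      if (abs(r - e) < 5e-4) break
      q <- q * e / r
    }
  })
  .calib_cache[[key]] <- q
  q
}

## Genome-oriented truth CIGAR for one read. keep/ins are per-source-base
## (transcript orientation); gpos gives each source base's genome position.
truth_cigar <- function(keep, ins, gpos, gene_strand) {
  n <- length(keep)
  ## column stream in transcript orientation: per base an M or D column,
  ## followed by an I column when an insertion was made after it
  ncol_per <- 1L + as.integer(ins)
  ops <- character(sum(ncol_per))
  colg <- rep(NA_integer_, sum(ncol_per))
  at <- cumsum(ncol_per) - ncol_per + 1L
  ops[at] <- ifelse(keep, "M", "D")
  colg[at] <- gpos
  ops[ops == ""] <- "I"
  if (gene_strand == "-") { ops <- rev(ops); colg <- rev(colg) }
  ## insert N columns at genome jumps between consecutive M/D columns
  ref_idx <- which(!is.na(colg))
  jumps <- which(diff(colg[ref_idx]) > 1L)
  len <- rep(1L, length(ops))
  if (length(jumps)) {
    ## splice N ops in after ref column ref_idx[jumps]
    ins_at <- ref_idx[jumps]
    nlen <- colg[ref_idx[jumps + 1L]] - colg[ref_idx[jumps]] - 1L
    ord <- order(c(seq_along(ops), ins_at + 0.5))
    ops <- c(ops, rep("N", length(ins_at)))[ord]
    len <- c(len, nlen)[ord]
  }
  cigar_string(len, ops)
}

#' Simulate long reads from transcripts with ground truth
#'
#' Per transcript, reads are drawn until the cumulative base count reaches
#' depth x transcript length (depth per the expression profile). Read
#' length is drawn from the model's gamma distribution truncated at the
#' transcript length; start positions are uniform; reads are sampled
#' equally from both strands of the transcript. Errors are injected per
#' base (substitution to a uniformly different base, uniform insertions,
#' deletions) with the model's mix. Every read carries a truth record with
#' the genomic exon intervals it covers and its exact genome-oriented
#' alignment CIGAR.
#'
#' @param transcripts named character vector from [make_transcripts()].
#' @param profile expression profile from [assign_expression()] (or any
#'   data.frame with transcript_id and depth).
#' @param model an [error_model()] (or a compatible list).
#' @param annotation the `gene_annotation` the transcripts came from.
#' @param seed RNG seed.
#' @param min_read_len minimum simulated read length (default 100).
#' @param max_reads optional cap on the total number of reads.
#' @return list(reads, truth): a read data.frame (id, seq, qual) and a
#'   truth data.frame ready for [write_truth()].
#' @export
simulate_reads <- function(transcripts, profile, model, annotation,
                           seed = 1L, min_read_len = 100L,
                           max_reads = NULL) {
  stopifnot(model$e >= 0, model$e < 1, abs(sum(model$mix) - 1) < 1e-9)
  q <- calibrate_event_rate(model$e, model$mix)
  ## the length distribution describes the read as emitted; deletions and
  ## insertions rescale the emitted length relative to the source span by
  ## this factor, so the drawn length is converted back to a source length
  len_factor <- 1 + q * (model$mix[["ins"]] - model$mix[["del"]])
  with_seed(seed, {
    shape <- 1 / model$cv^2
    scale <- model$mean_len / shape
    ids <- character(0); seqs <- character(0)
    t_id <- character(0); t_chrom <- character(0); t_strand <- character(0)
    t_exons <- character(0); t_cigar <- character(0); t_tx <- character(0)
    total <- 0L
    for (tx in profile$transcript_id) {
      tseq <- transcripts[[tx]]
      L <- nchar(tseq)
      depth <- profile$depth[profile$transcript_id == tx][1]
      map <- tx_map(annotation, tx)
      gene_strand <- map$strand[1]
      chrom <- map$chrom[1]
      target <- depth * L
      cum <- 0
      i <- 0L
      while (cum < target) {
        i <- i + 1L
        rl <- round(rgamma(1, shape = shape, scale = scale) / len_factor)
        rl <- max(min(rl, L), min(min_read_len, L))
        a <- sample.int(L - rl + 1L, 1L) - 1L
        src <- substr(tseq, a + 1L, a + rl)
        inj <- inject_errors(src, q, model$mix)
        read_strand <- sample(c("+", "-"), 1L)
        emitted <- if (read_strand == "+") inj$read else revcomp(inj$read)
        ## genome positions of the source bases (transcript orientation)
        toff <- a + seq_len(rl) - 1L
        ei <- findInterval(toff, map$tx_start)
        gpos <- if (gene_strand == "+")
          map$start[ei] + (toff - map$tx_start[ei])
        else
          map$end[ei] - 1L - (toff - map$tx_start[ei])
        truth_strand <- if (gene_strand == read_strand) "+" else "-"
        gsorted <- sort(gpos)
        brk <- c(0L, which(diff(gsorted) > 1L), length(gsorted))
        ex_str <- paste(vapply(seq_len(length(brk) - 1L), function(j) {
          seg <- gsorted[(brk[j] + 1L):brk[j + 1L]]
          paste0(seg[1], "-", seg[length(seg)] + 1L)
        }, character(1)), collapse = ",")
        rid <- sprintf("%s_r%04d", tx, i)
        ids <- c(ids, rid); seqs <- c(seqs, emitted)
        t_id <- c(t_id, rid); t_tx <- c(t_tx, tx)
        t_chrom <- c(t_chrom, chrom); t_strand <- c(t_strand, truth_strand)
        t_exons <- c(t_exons, ex_str)
        t_cigar <- c(t_cigar, truth_cigar(inj$keep, inj$ins, gpos,
                                          gene_strand))
        cum <- cum + nchar(emitted)
        total <- total + 1L
        if (!is.null(max_reads) && total >= max_reads) break
      }
      if (!is.null(max_reads) && total >= max_reads) break
    }
    reads <- data.frame(id = ids, seq = seqs,
                        qual = vapply(nchar(seqs),
                                      function(n) strrep("I", n),
                                      character(1)),
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = t_id, transcript_id = t_tx,
                        chrom = t_chrom, strand = t_strand,
                        exons = t_exons, cigar = t_cigar,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}
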