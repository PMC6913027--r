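# Shared fixtures (built lazily, cached for the whole run) and independent
# oracles used across test files.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## The 20-gene world of the end-to-end checks: exons 20-300 bp, introns
## 200-5000 bp, 2-10 exons per gene.
world20 <- function() fixture("world20", function() {
  spec <- gene_model_spec(n_genes = 20, exon_count = c(2L, 10L),
                          exon_len = c(20L, 300L),
                          intron_len = c(200L, 5000L))
  g <- generate_genome(spec, seed = 11)
  tx <- make_transcripts(g$annotation, g$reference)
  list(genome = g$reference, annotation = g$annotation, tx = tx)
})

## Error-free 10x reads over world20 plus their two-pass alignment.
world20_clean_aln <- function() fixture("world20_clean_aln", function() {
  w <- world20()
  prof <- assign_expression(w$annotation, seed = 11, d_high = 10, d_low = 10)
  em <- error_model("pacbio-subread"); em$e <- 0
  sim <- simulate_reads(w$tx, prof, em, w$annotation, seed = 12)
  aln <- align_all(w$genome, sim$reads, pipeline_config())
  list(sim = sim, aln = aln)
})

## 15% error (PacBio subread model) 30x reads over world20 plus alignment.
world20_noisy_aln <- function() fixture("world20_noisy_aln", function() {
  w <- world20()
  prof <- assign_expression(w$annotation, seed = 11, d_high = 30, d_low = 30)
  em <- error_model("pacbio-subread")
  sim <- simulate_reads(w$tx, prof, em, w$annotation, seed = 13)
  aln <- align_all(w$genome, sim$reads, pipeline_config())
  list(sim = sim, aln = aln)
})

## A small single-gene world used by cheap end-to-end unit tests.
world3exon <- function() fixture("world3exon", function() {
  spec <- gene_model_spec(n_genes = 1, exon_count = c(3L, 3L),
                          exon_len = c(60L, 120L),
                          intron_len = c(200L, 600L),
                          multi_isoform_frac = 0)
  g <- generate_genome(spec, seed = 5)
  tx <- make_transcripts(g$annotation, g$reference)
  list(genome = g$reference, annotation = g$annotation, tx = tx)
})

## ---- independent oracles ---------------------------------------------------

## Full affine-gap semi-global DP (score only), O(mn), kept deliberately
## independent of the package implementation.
oracle_semiglobal_score <- function(q, r, match = 2, mismatch = -4,
                                    go = -4, ge = -2) {
  m <- nchar(q); n <- nchar(r)
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  NEG <- -1e9
  H <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in query (consumes reference)
  F <- matrix(NEG, m + 1, n + 1)  # gap in reference (consumes query)
  H[1, ] <- 0
  for (i in 2:(m + 1)) {
    F[i, 1] <- max(H[i - 1, 1] + go + ge, F[i - 1, 1] + ge)
    H[i, 1] <- F[i, 1]
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + go + ge, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go + ge, F[i - 1, j] + ge)
      d <- H[i - 1, j - 1] + if (qc[i - 1] == rc[j - 1]) match else mismatch
      H[i, j] <- max(d, E[i, j], F[i, j])
    }
  }
  max(H[m + 1, ])
}

## Exhaustive best chain over a skeleton DAG by path enumeration.
oracle_best_chain <- function(dag) {
  mbs <- dag$mbs
  n <- nrow(mbs)
  vw <- mbs$re - mbs$rs
  adj <- split(seq_len(nrow(dag$edges)), dag$edges$from)
  best <- -Inf
  rec <- function(v, sc) {
    best <<- max(best, sc)
    for (e in adj[[as.character(v)]])
      rec(dag$edges$to[e], sc + dag$edges$w[e])
  }
  for (v in seq_len(n)) rec(v, vw[v])
  best
}

## Naive full-text l-mer search over the unitig set.
oracle_lookup <- function(unitigs, seed) {
  hits <- list()
  for (u in seq_along(unitigs)) {
    p <- gregexpr(seed, unitigs[u], fixed = TRUE)[[1]]
    ## gregexpr misses overlapping matches; rescan manually
    L <- nchar(unitigs[u]); l <- nchar(seed)
    offs <- which(vapply(seq_len(max(0, L - l + 1)), function(i)
      substr(unitigs[u], i, i + l - 1) == seed, logical(1))) - 1L
    if (length(offs))
      hits[[length(hits) + 1]] <- data.frame(uid = u, uoff = offs)
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(uid = integer(0), uoff = integer(0)) else out
}

## Brute-force de Bruijn k-mer set of a genome (N-free).
oracle_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1), k:n)
    out <- c(out, km[!grepl("N", km, fixed = TRUE)])
  }
  unique(out)
}

## Write a small SAM from truth records directly (truth-perfect alignment).
truth_perfect_sam <- function(truth, reads) {
  idx <- match(truth$read_id, reads$id)
  data.frame(qname = truth$read_id,
             flag = ifelse(truth$strand == "-", 16L, 0L),
             chrom = truth$chrom,
             pos = vapply(truth$exons, function(e)
               splicewalk:::truth_exons(e)$start[1], integer(1)),
             mapq = 60L,
             cigar = truth$cigar,
             seq = ifelse(truth$strand == "-", revcomp(reads$seq[idx]),
                          reads$seq[idx]),
             qual = NA_character_, score = 0,
             stringsAsFactors = FALSE)
}
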