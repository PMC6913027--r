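test_that("generate_genome is deterministic and honours the gene model", {
  spec <- gene_model_spec(n_genes = 10, exon_count = c(2, 5),
                          multi_isoform_frac = 1)
  g1 <- generate_genome(spec, seed = 42)
  g2 <- generate_genome(spec, seed = 42)
  expect_identical(g1$reference, g2$reference)
  expect_identical(g1$annotation$exons, g2$annotation$exons)

  ex <- g1$annotation$exons
  per_tx <- table(ex$transcript_id)
  primary <- per_tx[grepl("t1$", names(per_tx))]
  expect_true(all(primary >= 2 & primary <= 5))
  expect_equal(length(unique(ex$gene_id)), 10L)

  ## multi-isoform fraction 1: every gene has >= 2 isoforms sharing an exon
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid, ]
    expect_gte(length(unique(e$transcript_id)), 2L)
    key <- paste(e$start, e$end)
    expect_true(any(duplicated(key)))
  }

  ## introns carry canonical GT...AG
  e1 <- ex[ex$transcript_id == names(primary)[1], ]
  e1 <- e1[order(e1$start), ]
  if (nrow(e1) > 1) {
    for (i in seq_len(nrow(e1) - 1)) {
      expect_equal(substr(g1$reference[[1]], e1$end[i] + 1, e1$end[i] + 2),
                   "GT")
      expect_equal(substr(g1$reference[[1]], e1$start[i + 1] - 1,
                          e1$start[i + 1]), "AG")
    }
  }
})

test_that("antisense option nests an opposite-strand gene; budget errors out", {
  spec <- gene_model_spec(n_genes = 4, exon_count = c(3, 5),
                          intron_len = c(800, 2000),
                          antisense_overlap = TRUE)
  g <- generate_genome(spec, seed = 9)
  ex <- g$annotation$exons
  minus <- ex[ex$strand == "-", ]
  expect_gte(nrow(minus), 1L)
  plus <- ex[ex$strand == "+", ]
  tx_span <- range(plus$start[plus$gene_id == plus$gene_id[1]],
                   plus$end[plus$gene_id == plus$gene_id[1]])
  expect_true(any(minus$start >= tx_span[1] & minus$end <= tx_span[2]))

  spec2 <- gene_model_spec(n_genes = 50, chrom_budget = 1000L)
  expect_error(generate_genome(spec2, seed = 1), "budget")
})

test_that("make_transcripts concatenates exons strand-aware", {
  ref <- c(c1 = random_dna(500, 431))
  anno <- gene_annotation(data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    transcript_id = c("t1", "t1", "t2", "t2", "t3"),
    chrom = "c1", strand = c("+", "+", "-", "-", "+"),
    start = c(100L, 300L, 100L, 300L, 50L),
    end = c(150L, 360L, 150L, 360L, 80L)))
  tx <- make_transcripts(anno, ref)
  plus_concat <- paste0(substr(ref, 101, 150), substr(ref, 301, 360))
  expect_equal(unname(tx["t1"]), plus_concat)
  expect_equal(unname(tx["t2"]), revcomp(plus_concat))
  expect_equal(unname(tx["t3"]), unname(substr(ref, 51, 80)))
  expect_equal(nchar(tx[["t1"]]), 110L)

  bad <- gene_annotation(data.frame(gene_id = "g", transcript_id = "t",
                                    chrom = "c1", strand = "+",
                                    start = 400L, end = 600L))
  expect_error(make_transcripts(bad, ref), "bounds")
})

test_that("assign_expression marks one isoform per gene highly expressed", {
  anno <- gene_annotation(data.frame(
    gene_id = c("g1", "g1", "g1", "g2"),
    transcript_id = c("a", "b", "c", "d"),
    chrom = "c1", strand = "+",
    start = c(0L, 0L, 0L, 500L), end = c(100L, 100L, 100L, 600L)))
  p <- assign_expression(anno, seed = 3)
  g1 <- p[p$gene_id == "g1", ]
  expect_equal(sum(g1$label == "highly"), 1L)
  expect_equal(sum(g1$label == "lowly"), 2L)
  expect_equal(p$label[p$gene_id == "g2"], "highly")
  expect_equal(sort(unique(p$depth)), c(4, 30))
  expect_identical(assign_expression(anno, seed = 3),
                   assign_expression(anno, seed = 3))
})

test_that("error-free simulation yields exact substrings with tiling truth", {
  w <- world3exon()
  prof <- assign_expression(w$annotation, seed = 5, d_high = 5, d_low = 5)
  em <- error_model("pacbio-roi"); em$e <- 0
  sim <- simulate_reads(w$tx, prof, em, w$annotation, seed = 8)
  expect_gt(nrow(sim$reads), 0)
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[i, ]
    te <- splicewalk:::truth_exons(tr$exons)
    src <- paste(substring(w$genome[[tr$chrom]], te$start + 1, te$end),
                 collapse = "")
    q <- if (tr$strand == "+") sim$reads$seq[i] else revcomp(sim$reads$seq[i])
    expect_identical(q, src)                       # exact transcript substring
    expect_equal(sum(te$end - te$start), nchar(q)) # truth tiles the read
    ## truth CIGAR is all M/N for error-free reads
    expect_false(grepl("[ID]", tr$cigar))
  }
})

test_that("the depth stopping rule lands within one read of the target", {
  tx <- c(t1 = random_dna(1000, 433))
  anno <- gene_annotation(data.frame(gene_id = "g", transcript_id = "t1",
                                     chrom = "c1", strand = "+",
                                     start = 0L, end = 1000L))
  prof <- data.frame(transcript_id = "t1", depth = 30)
  em <- error_model("pacbio-roi"); em$e <- 0
  sim <- simulate_reads(tx, prof, em, anno, seed = 10)
  total <- sum(nchar(sim$reads$seq))
  expect_gte(total, 29000)
  expect_lte(total, 31000)
})

test_that("simulation is byte-deterministic under the seed", {
  w <- world3exon()
  prof <- assign_expression(w$annotation, seed = 5, d_high = 4, d_low = 4)
  em <- error_model("ont-2d")
  s1 <- simulate_reads(w$tx, prof, em, w$annotation, seed = 99)
  s2 <- simulate_reads(w$tx, prof, em, w$annotation, seed = 99)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_reads(w$tx, prof, em, w$annotation, seed = 100)
  expect_false(identical(s1$reads$seq, s3$reads$seq))
})

test_that("a custom error model realises its configured rate", {
  ## e = 0.15 with mix (0.4, 0.3, 0.3): realized edit-distance rate within
  ## +-0.01 (Monte-Carlo over ~100 kb of simulated bases)
  tx <- c(t1 = random_dna(20000, 439))
  anno <- gene_annotation(data.frame(gene_id = "g", transcript_id = "t1",
                                     chrom = "c1", strand = "+",
                                     start = 0L, end = 20000L))
  prof <- data.frame(transcript_id = "t1", depth = 5)
  model <- structure(list(name = "custom", e = 0.15,
                          mix = c(sub = 0.4, ins = 0.3, del = 0.3),
                          mean_len = 2000, cv = 0.35),
                     class = "error_model")
  sim <- simulate_reads(tx, prof, model, anno, seed = 12)
  rates <- read_error_rate(sim$reads, sim$truth, c(c1 = tx[["t1"]]))
  expect_lt(abs(mean(rates) - 0.15), 0.01)
})

test_that("truth CIGARs place every base consistently with the genome", {
  w <- world3exon()
  prof <- assign_expression(w$annotation, seed = 5, d_high = 4, d_low = 4)
  em <- error_model("pacbio-subread")
  sim <- simulate_reads(w$tx, prof, em, w$annotation, seed = 14)
  gen <- w$genome[[1]]
  for (i in seq_len(min(10, nrow(sim$reads)))) {
    tr <- sim$truth[i, ]
    te <- splicewalk:::truth_exons(tr$exons)
    q <- if (tr$strand == "+") sim$reads$seq[i] else revcomp(sim$reads$seq[i])
    bp <- splicewalk:::cigar_base_positions(te$start[1], tr$cigar)
    expect_equal(length(bp), nchar(q))
    mi <- !is.na(bp)
    qc <- strsplit(q, "")[[1]]
    gc <- strsplit(gen, "")[[1]][bp[mi] + 1]
    ## only substituted bases disagree; well below the raw error rate x2
    expect_gt(mean(qc[mi] == gc), 0.9)
  }
})
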