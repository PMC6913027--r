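test_that("predicted_exons parses spliced CIGARs", {
  e1 <- predicted_exons(100L, "50M150N60M")
  expect_equal(e1$start, c(100L, 300L))
  expect_equal(e1$end, c(150L, 360L))

  e2 <- predicted_exons(10L, "100M")
  expect_equal(nrow(e2), 1L)
  expect_equal(c(e2$start, e2$end), c(10L, 110L))

  ## D consumes reference within an exon; I does not
  e3 <- predicted_exons(0L, "20M5D25M100N30M")
  expect_equal(e3$start, c(0L, 150L))
  expect_equal(e3$end, c(50L, 180L))
  e4 <- predicted_exons(0L, "20M5I25M100N30M")
  expect_equal(e4$end, c(45L, 175L))
})

## a two-read toy world with hand-computed expectations
toy_eval <- function() {
  truth <- data.frame(
    read_id = c("r1", "r2"),
    transcript_id = "t", chrom = "c1", strand = "+",
    exons = c("100-150,300-360", "500-540,700-750,900-940,1100-1150,1300-1350"),
    cigar = c("50M150N60M", "40M160N50M150N40M160N50M150N50M"),
    stringsAsFactors = FALSE)
  reads <- data.frame(id = c("r1", "r2"),
                      seq = c(strrep("A", 110), strrep("A", 230)),
                      qual = NA_character_, stringsAsFactors = FALSE)
  list(truth = truth, reads = reads)
}

test_that("sim_metrics is exact on a truth-perfect SAM", {
  t <- toy_eval()
  sam <- truth_perfect_sam(t$truth, t$reads)
  m <- sim_metrics(sam, t$truth)
  expect_equal(m$base_pct, 1)
  expect_equal(m$exon_pct, 1)
  expect_equal(m$read80_pct, 1)
  expect_equal(m$read100_pct, 1)
})

test_that("Read80 uses the strict >80% rule and the 5 bp boundary tolerance", {
  t <- toy_eval()
  sam <- truth_perfect_sam(t$truth, t$reads)
  ## r2: shift the middle exon by 10 bp -> N_G = 5, N_P = 5, N_T = 4
  ## 4/5 = 0.8 is NOT > 0.8, so r2 is neither Read80 nor Read100
  sam$cigar[2] <- "40M160N50M160N40M150N50M150N50M"
  m <- sim_metrics(sam, t$truth)
  d <- m$detail
  expect_equal(d$N_T[d$read_id == "r2"], 4L)
  expect_false(d$read80[d$read_id == "r2"])
  expect_equal(m$read80_pct, 0.5)

  ## a boundary off by exactly 6 bp misses; off by 5 bp still matches
  sam6 <- truth_perfect_sam(t$truth, t$reads)
  sam6$cigar[1] <- "44M156N60M"                    # first exon end -6
  m6 <- sim_metrics(sam6, t$truth)
  expect_equal(m6$detail$N_T[1], 1L)
  sam5 <- truth_perfect_sam(t$truth, t$reads)
  sam5$cigar[1] <- "45M155N60M"                    # first exon end -5
  m5 <- sim_metrics(sam5, t$truth)
  expect_equal(m5$detail$N_T[1], 2L)

  ## unmapped reads keep their bases and exons in the denominators
  samu <- truth_perfect_sam(t$truth, t$reads)
  samu$flag[2] <- 4L
  mu <- sim_metrics(samu, t$truth)
  expect_equal(mu$read100_pct, 0.5)
  expect_equal(mu$base_pct, 110 / 340)
  expect_true(mu$read100_pct <= mu$read80_pct)

  expect_error(sim_metrics(samu[1, ], t$truth[2, ]), "missing truth")
})

test_that("anno_metrics reproduces hand-computed counts", {
  anno <- gene_annotation(data.frame(
    gene_id = "g", transcript_id = c("t", "t", "t"), chrom = "c1",
    strand = "+", start = c(100L, 300L, 500L), end = c(150L, 325L, 600L)))
  sam <- data.frame(
    qname = c("a", "b", "c", "d"),
    flag = c(0L, 0L, 256L, 4L),
    chrom = c("c1", "c1", "c1", "*"),
    pos = c(100L, 141L, 100L, 0L),
    mapq = 60L,
    cigar = c("50M150N25M", "9M", "50M", "*"),
    seq = c(strrep("A", 75), strrep("A", 9), strrep("A", 50),
            strrep("A", 20)),
    qual = NA_character_, score = 1, stringsAsFactors = FALSE)
  m <- anno_metrics(sam, anno, xs = c(20L, 30L, 60L))
  ## primary mapped: a (two exons, both exact) and b (9 bp overlap)
  expect_equal(m$baseA, 75 + 9)
  expect_equal(m$baseGA, 75 + 9)                  # b lies inside exon 1
  expect_equal(m$exonP, 3L)
  ## b's 9 bp exon overlaps an annotated exon by 9 < 10: not ExonGO
  expect_equal(m$exonGO, 2L)
  expect_equal(m$exonGA, 2L)
  ## the 25 bp matched exon counts in ExonGA(30)/(60) but not ExonGA(20)
  expect_equal(unname(m$exonGA_by_len), c(0L, 1L, 2L))
  ## a: junction matches annotation; b: unspliced counts vacuously
  expect_equal(m$readGA, 2L)
  m2 <- anno_metrics(sam, anno, count_unspliced = FALSE)
  expect_equal(m2$readGA, 1L)

  bad <- sam; bad$chrom[1] <- "c9"
  expect_error(anno_metrics(bad, anno), "absent from annotation")
})

test_that("metrics are invariant to record order", {
  t <- toy_eval()
  sam <- truth_perfect_sam(t$truth, t$reads)
  sam$cigar[2] <- "40M160N50M160N40M150N50M150N50M"
  m1 <- sim_metrics(sam, t$truth)
  m2 <- sim_metrics(sam[2:1, ], t$truth)
  expect_equal(m1$base_pct, m2$base_pct)
  expect_equal(m1$exon_pct, m2$exon_pct)
  expect_equal(m1$read80_pct, m2$read80_pct)
})

test_that("truth-perfect SAM gives exonGA equal to exonP", {
  w <- world3exon()
  prof <- assign_expression(w$annotation, seed = 5, d_high = 3, d_low = 3)
  em <- error_model("pacbio-roi"); em$e <- 0
  sim <- simulate_reads(w$tx, prof, em, w$annotation, seed = 15)
  sam <- truth_perfect_sam(sim$truth, sim$reads)
  m <- anno_metrics(sam, w$annotation)
  expect_equal(m$exonGA, m$exonP)
  sm <- sim_metrics(sam, sim$truth)
  expect_equal(c(sm$base_pct, sm$exon_pct, sm$read80_pct, sm$read100_pct),
               c(1, 1, 1, 1))
})
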