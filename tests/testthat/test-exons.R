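mk_skel <- function(chrom, gs, ge, rs = NULL) {
  len <- ge - gs
  if (is.null(rs)) rs <- c(0L, cumsum(len))[seq_along(gs)]
  list(chrom = chrom, strand = "+", score = sum(len),
       mbs = data.frame(rs = rs, re = rs + len, chrom = chrom,
                        gs = gs, ge = ge, strand = "+"))
}

test_that("project_skeletons counts MB footprints and bridges short gaps", {
  p1 <- project_skeletons(list(mk_skel("c1", 100L, 150L)),
                          chrom_lens = c(c1 = 400L))
  v <- as.vector(p1$cov$c1)
  expect_equal(sum(v), 50)
  expect_true(all(v[101:150] == 1))

  p2 <- project_skeletons(list(mk_skel("c1", 100L, 150L),
                               mk_skel("c1", 120L, 180L)),
                          chrom_lens = c(c1 = 400L))
  expect_true(all(as.vector(p2$cov$c1)[121:150] == 2))

  ## 10 bp gap between two MBs of one skeleton is bridged (10 < 20)
  p3 <- project_skeletons(list(mk_skel("c1", c(100L, 160L), c(150L, 200L))),
                          chrom_lens = c(c1 = 400L))
  expect_true(all(as.vector(p3$cov$c1)[151:160] == 1))
  ## a 100 bp gap is not
  p4 <- project_skeletons(list(mk_skel("c1", c(100L, 250L), c(150L, 300L))),
                          chrom_lens = c(c1 = 400L))
  expect_true(all(as.vector(p4$cov$c1)[151:250] == 0))
})

test_that("combine_regions merges nearby runs and injects annotation", {
  prof <- project_skeletons(list(mk_skel("c1", c(100L, 205L), c(200L, 300L),
                                         rs = c(0L, 105L))),
                            bridge = 1L, chrom_lens = c(c1 = 600L))
  d <- combine_regions(prof, join_gap = 10L)
  expect_equal(nrow(d), 1L)                       # gap 5 < 10: merged
  expect_equal(c(d$start, d$end), c(100L, 300L))

  prof2 <- project_skeletons(list(mk_skel("c1", c(100L, 300L), c(200L, 400L),
                                          rs = c(0L, 100L))),
                             bridge = 1L, chrom_lens = c(c1 = 600L))
  d2 <- combine_regions(prof2, join_gap = 10L)
  expect_equal(nrow(d2), 2L)

  anno <- gene_annotation(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c1", strand = "+",
    start = 150L, end = 250L))
  prof3 <- project_skeletons(list(mk_skel("c1", 100L, 200L)),
                             chrom_lens = c(c1 = 600L))
  d3 <- combine_regions(prof3, annotation = anno)
  expect_equal(nrow(d3), 1L)
  expect_equal(c(d3$start, d3$end), c(100L, 250L))
  expect_equal(d3$source, "both")

  ## outputs are disjoint and sorted; annotation never removes a read draft
  d4 <- combine_regions(prof2, annotation = anno)
  expect_true(all(diff(d4$start) > 0))
  expect_true(all(d4$start[-1] >= d4$end[-nrow(d4)]))
  for (i in seq_len(nrow(d2)))
    expect_true(any(d4$start <= d2$start[i] & d4$end >= d2$end[i]))
})

test_that("filter_draft_exons drops short or weak drafts but spares annotation", {
  drafts <- data.frame(chrom = "c1",
                       start = c(0L, 100L, 200L, 300L),
                       end = c(8L, 180L, 290L, 400L),
                       coverage = c(5, 0.5, 3, 0),
                       source = c("reads", "reads", "reads", "annotation"))
  out <- filter_draft_exons(drafts, min_len = 10L, min_cov = 1)
  expect_equal(out$start, c(200L, 300L))           # len 8 and cov 0.5 removed
})

test_that("refine_boundaries snaps to canonical splice sites near the draft", {
  ## construct: intron ends with AG right before the true exon start, and
  ## GT starts right after the true exon end; draft offset +4 / -3
  ct_dna <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("C", "G"), n, replace = TRUE), collapse = "")
  }
  left <- ct_dna(60, 211); right <- ct_dna(60, 223)
  exon <- ct_dna(80, 227)
  seqc <- paste0(substr(left, 1, 58), "AG", exon, "GT", substr(right, 1, 58))
  ref <- c(c1 = seqc)
  tstart <- 60L; tend <- 140L                      # true exon, 0-based
  drafts <- data.frame(chrom = "c1", start = tstart + 4L, end = tend - 3L,
                       coverage = 5, source = "reads")
  out <- refine_boundaries(drafts, ref)
  expect_equal(c(out$start, out$end), c(tstart, tend))

  ## W = 0 degenerates to the draft
  out0 <- refine_boundaries(drafts, ref, model = splice_model(W = 0))
  expect_equal(c(out0$start, out0$end), c(tstart + 4L, tend - 3L))

  ## refinement that would empty the exon falls back to the draft
  tiny <- data.frame(chrom = "c1", start = 70L, end = 72L,
                     coverage = 5, source = "reads")
  outt <- refine_boundaries(tiny, ref)
  expect_true(outt$end > outt$start)
})

test_that("infer_exons recovers true exons from pooled error-free skeletons", {
  w <- world3exon()
  idx <- build_index(w$genome)
  prof <- assign_expression(w$annotation, seed = 5, d_high = 10, d_low = 10)
  em <- error_model("pacbio-roi"); em$e <- 0
  sim <- simulate_reads(w$tx, prof, em, w$annotation, seed = 6)
  skels <- unlist(lapply(sim$reads$seq, function(s) read_skeletons(idx, s)),
                  recursive = FALSE)
  ex <- infer_exons(skels, w$genome)
  true_ex <- unique(w$annotation$exons[, c("start", "end")])
  true_ex <- true_ex[order(true_ex$start), ]
  ## splice-facing (internal) boundaries must be exact to within 5 bp;
  ## transcript-terminal boundaries carry no splice signal, so refinement
  ## may shift them within its window (downstream cleanup makes that
  ## harmless in alignments)
  for (i in seq_len(nrow(true_ex))) {
    hit <- any(abs(ex$start - true_ex$start[i]) <= 16 &
                 abs(ex$end - true_ex$end[i]) <= 16)
    expect_true(hit, info = paste("exon", true_ex$start[i]))
    if (i > 1)
      expect_true(any(abs(ex$start - true_ex$start[i]) <= 5),
                  info = paste("acceptor", true_ex$start[i]))
    if (i < nrow(true_ex))
      expect_true(any(abs(ex$end - true_ex$end[i]) <= 5),
                  info = paste("donor", true_ex$end[i]))
  }
})
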