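test_that("extract_seeds samples the stated offsets and skips N windows", {
  r100 <- random_dna(100, 7)
  s <- extract_seeds(r100, l = 15, m = 5)
  expect_equal(nrow(s), 18L)                      # floor((100-15)/5)+1
  expect_equal(s$offset, seq(0L, 85L, by = 5L))
  expect_equal(nrow(extract_seeds(random_dna(14, 7), l = 15)), 0L)
  withN <- paste0("ACGT", "N", random_dna(95, 9))
  sN <- extract_seeds(withN, l = 15, m = 5)
  expect_false(0L %in% sN$offset)                 # first window contains N
})

test_that("find_umems recovers exact containment and splits at substitutions", {
  ref <- c(c1 = random_dna(2000, 101))
  idx <- build_index(ref, k = 22, l = 15)
  read <- substr(ref, 501, 700)
  um <- find_umems(idx, read)
  expect_equal(nrow(um), 1L)
  expect_equal(c(um$rs, um$re), c(0L, 200L))

  ## one substitution at read position p: two abutting U-MEMs, neither
  ## containing p
  p <- 100L
  mut <- read
  old <- substr(mut, p + 1, p + 1)
  substr(mut, p + 1, p + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  um2 <- find_umems(idx, mut)
  expect_equal(nrow(um2), 2L)
  expect_true(all(um2$re <= p | um2$rs >= p + 1))
  expect_setequal(c(um2$rs, um2$re), c(0L, p, p + 1L, 200L))

  ## substring equality invariant on random noisy reads
  set.seed(55)
  for (rep in 1:5) {
    a <- sample(1500, 1)
    rd <- unname(substr(ref, a, a + 150))
    for (q in sample(150, 6)) {
      b <- substr(rd, q, q)
      substr(rd, q, q) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
    um3 <- find_umems(idx, rd)
    for (i in seq_len(nrow(um3))) {
      u <- idx$unitigs[um3$uid[i]]
      expect_equal(unname(substr(rd, um3$rs[i] + 1, um3$re[i])),
                   unname(substr(u, um3$us[i] + 1, um3$ue[i])))
    }
  }
})

test_that("merge_sumems merges same-diagonal blocks within the slack", {
  um <- data.frame(rs = c(0L, 12L), re = c(10L, 20L), uid = c(1L, 1L),
                   us = c(5L, 17L), ue = c(15L, 25L))
  m <- merge_sumems(um, slack = 2)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$rs, m$re, m$us, m$ue), c(0L, 20L, 5L, 25L))

  um$uid[2] <- 2L                                  # different unitigs
  expect_equal(nrow(merge_sumems(um, slack = 2)), 2L)

  um$uid[2] <- 1L
  um$us[2] <- 22L                                  # diagonal differs by 5
  expect_equal(nrow(merge_sumems(um, slack = 2)), 2L)
})

test_that("project_to_mbs yields one MB per occurrence with substring equality", {
  block <- random_dna(80, 103)
  ref <- c(c1 = paste0(random_dna(200, 107), block, random_dna(200, 109),
                       block, random_dna(200, 113), block,
                       random_dna(100, 127)))
  idx <- build_index(ref, k = 13, l = 9)
  read <- block
  um <- find_umems(idx, read)
  mbs <- project_to_mbs(idx, merge_sumems(um))
  ## the 80 bp block occurs at 3 genomic loci
  full <- mbs[mbs$re - mbs$rs == 80, ]
  expect_equal(nrow(full), 3L)
  for (i in seq_len(nrow(mbs)))
    expect_equal(substr(ref[[1]], mbs$gs[i] + 1, mbs$ge[i]),
                 substr(read, mbs$rs[i] + 1, mbs$re[i]))
})

test_that("build_dag respects co-linearity and the maximum intron length", {
  mbs <- data.frame(rs = c(0L, 60L), re = c(50L, 110L),
                    chrom = "c1", gs = c(1000L, 2050L),
                    ge = c(1050L, 2100L), strand = "+")
  dag <- build_dag(mbs)                            # genomic gap 1000
  expect_equal(nrow(dag$edges), 1L)

  mbs$gs[2] <- 1050L + 250000L; mbs$ge[2] <- mbs$gs[2] + 50L
  expect_equal(nrow(build_dag(mbs)$edges), 0L)     # gap 250000 > T_intron

  mbs2 <- data.frame(rs = c(0L, 60L), re = c(50L, 110L), chrom = "c1",
                     gs = c(2000L, 1000L), ge = c(2050L, 1050L),
                     strand = "+")                 # inverted genomic order
  expect_equal(nrow(build_dag(mbs2)$edges), 0L)
})

test_that("sdp_chain equals exhaustive path enumeration on small DAGs", {
  sk <- sdp_chain(build_dag(data.frame(rs = 0L, re = 40L, chrom = "c1",
                                       gs = 100L, ge = 140L, strand = "+")))
  expect_length(sk, 1L)
  expect_equal(sk[[1]]$score, 40)

  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    rs <- sort(sample(0:400, n))
    len <- sample(10:40, n, replace = TRUE)
    gs <- sort(sample(0:5000, n))
    mbs <- data.frame(rs = rs, re = rs + len, chrom = "c1",
                      gs = gs, ge = gs + len, strand = "+")
    dag <- build_dag(mbs)
    got <- sdp_chain(dag)
    expect_equal(got[[1]]$score, oracle_best_chain(dag), tolerance = 1e-9)
  }
})

test_that("near-best skeletons at distinct loci are both reported", {
  ## two disjoint loci scoring 100 and 97: with epsilon = 0.05 both are kept
  mbs <- data.frame(rs = c(0L, 0L), re = c(100L, 97L), chrom = "c1",
                    gs = c(1000L, 50000L), ge = c(1100L, 50097L),
                    strand = "+")
  sks <- sdp_chain(build_dag(mbs), epsilon = 0.05)
  expect_length(sks, 2L)
  expect_equal(sort(vapply(sks, `[[`, numeric(1), "score")), c(97, 100))
})

test_that("sdp_chain score never decreases when an MB is added", {
  set.seed(83)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    rs <- sort(sample(0:300, n + 1))
    len <- sample(10:30, n + 1, replace = TRUE)
    gs <- sort(sample(0:3000, n + 1))
    mbs <- data.frame(rs = rs, re = rs + len, chrom = "c1", gs = gs,
                      ge = gs + len, strand = "+")
    s_small <- sdp_chain(build_dag(mbs[1:n, ]))[[1]]$score
    s_big <- sdp_chain(build_dag(mbs))[[1]]$score
    expect_gte(s_big, s_small)
  }
})

test_that("skeletons are strictly co-linear and cover error-free single-exon reads", {
  ref <- c(c1 = random_dna(8000, 131))
  idx <- build_index(ref)
  set.seed(61)
  for (rep in 1:8) {
    a <- sample(6000, 1)
    read <- substr(ref, a, a + 299)
    sks <- read_skeletons(idx, read)
    expect_gte(length(sks), 1L)
    top <- sks[[1]]
    expect_gte(sum(top$mbs$re - top$mbs$rs) / 300, 0.95)
    mb <- top$mbs
    if (nrow(mb) > 1) {
      expect_true(all(diff(mb$rs) > 0 & diff(mb$gs) > 0))
      expect_true(all(mb$gs[-1] - mb$ge[-nrow(mb)] <= 200000))
    }
  }
})
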