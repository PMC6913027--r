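test_that("split_read partitions the read around its anchor MBs", {
  sk <- list(mbs = data.frame(rs = c(10L, 50L, 90L), re = c(30L, 70L, 110L)))
  p <- split_read(120L, sk)
  expect_equal(p$rs, c(0L, 30L, 70L, 110L))
  expect_equal(p$re, c(10L, 50L, 90L, 120L))
  expect_equal(p$left_mb, c(NA, 1L, 2L, 3L))
  expect_equal(p$right_mb, c(1L, 2L, 3L, NA))

  full <- list(mbs = data.frame(rs = 0L, re = 120L))
  expect_equal(nrow(split_read(120L, full)), 0L)

  mid <- list(mbs = data.frame(rs = 40L, re = 80L))
  pm <- split_read(120L, mid)
  expect_equal(pm$rs, c(0L, 80L))
  expect_equal(pm$re, c(40L, 120L))
})

test_that("find_hit_exons detects short spanning exons and rejects noise", {
  ref <- c(c1 = random_dna(3000, 301))
  exons <- data.frame(chrom = "c1", start = c(500L, 1500L),
                      end = c(521L, 1600L))
  part <- substr(ref, 501, 521)                    # the 21 bp exon, exact
  hits <- find_hit_exons(part, exons, ref, c(0L, 3000L), "c1", s = 8)
  expect_true(500L %in% hits$start)

  ## random parts essentially never hit unrelated 100 bp exons
  nhit <- 0L
  for (i in 1:30) {
    rpart <- random_dna(100, 400 + i)
    h <- find_hit_exons(rpart, exons[2, , drop = FALSE], ref,
                        c(0L, 3000L), "c1", s = 8)
    nhit <- nhit + nrow(h)
  }
  expect_lte(nhit, 6L)

  ## empty part: no sequence-evidence hits (anchors are added by the caller)
  expect_equal(nrow(find_hit_exons("", exons, ref, c(0L, 3000L), "c1")), 0L)
})

test_that("compose_lsrs stitches exons with an exact segment map", {
  ref <- c(c1 = random_dna(1000, 307))
  l <- compose_lsrs(data.frame(start = c(100L, 300L), end = c(150L, 360L)),
                    ref, "c1")
  expect_equal(nchar(l$seq), 110L)
  expect_equal(l$map$ls, c(0L, 50L))
  expect_equal(l$map$le, c(50L, 110L))
  expect_equal(l$seq, unname(paste0(substr(ref, 101, 150),
                              substr(ref, 301, 360))))

  single <- compose_lsrs(data.frame(start = 100L, end = 150L), ref, "c1")
  expect_equal(single$seq, unname(substr(ref, 101, 150)))

  merged <- compose_lsrs(data.frame(start = c(100L, 140L),
                                    end = c(150L, 200L)), ref, "c1")
  expect_equal(nrow(merged$map), 1L)
  expect_equal(c(merged$map$gs, merged$map$ge), c(100L, 200L))

  expect_error(compose_lsrs(data.frame(start = integer(0), end = integer(0)),
                            ref, "c1"), "empty exon set")
})

test_that("semiglobal_align matches identity and the worked 4x4 example", {
  r <- random_dna(60, 311)
  a <- semiglobal_align(r, r)
  expect_equal(a$score, 120)
  expect_equal(a$cigar, "60M")

  ## ACGT vs AGGT: best is 4M with one mismatch = 2 - 4 + 2 + 2 = 2
  a2 <- semiglobal_align("ACGT", "AGGT")
  expect_equal(a2$score, 2)
  expect_equal(a2$cigar, "4M")
})

test_that("semiglobal_align equals the full-DP oracle on random pairs", {
  set.seed(313)
  for (rep in 1:30) {
    q <- random_dna(sample(5:50, 1), 1000 + rep)
    r <- random_dna(sample(5:50, 1), 2000 + rep)
    got <- semiglobal_align(q, r)
    expect_equal(got$score, oracle_semiglobal_score(q, r),
                 info = paste("pair", rep))
    ## CIGAR consistency: consumes the whole query
    co <- cigar_ops(got$cigar)
    expect_equal(sum(co$len[co$op %in% c("M", "I")]), nchar(q))
  }
})

test_that("realign_large_deletions excises unused alternative extensions", {
  ## LSRS contains an exon with an unused alternative 5' extension of 40 bp:
  ## pass one leaves a 40D run; excision creates a junction and removes it
  exA <- random_dna(80, 331); ext <- random_dna(40, 337)
  exB <- random_dna(80, 347)
  ref <- c(c1 = paste0(random_dna(50, 349), exA, ext,
                       random_dna(300, 353), exB, random_dna(50, 359)))
  lsrs <- compose_lsrs(data.frame(start = c(50L, 470L),
                                  end = c(170L, 550L)), ref, "c1")
  query <- paste0(exA, exB)                        # skips the extension
  aln <- semiglobal_align(query, lsrs$seq)
  expect_true(any(cigar_ops(aln$cigar)$op == "D" &
                    cigar_ops(aln$cigar)$len >= 30))
  res <- realign_large_deletions(aln, lsrs, query)
  co <- cigar_ops(res$aln$cigar)
  expect_false(any(co$op == "D" & co$len >= 30))
  expect_gte(res$aln$score + 0.01, aln$score)

  ## small deletions are untouched
  q2 <- paste0(substr(exA, 1, 40), substr(exA, 53, 80))  # 12 bp deletion
  l2 <- compose_lsrs(data.frame(start = 50L, end = 130L), ref, "c1")
  a2 <- semiglobal_align(q2, l2$seq)
  r2 <- realign_large_deletions(a2, l2, q2)
  expect_identical(r2$aln$cigar, a2$cigar)
})

test_that("lift_to_genome inserts N at junctions and conserves query ops", {
  ref <- c(c1 = random_dna(1000, 367))
  lsrs <- compose_lsrs(data.frame(start = c(100L, 300L),
                                  end = c(150L, 360L)), ref, "c1")
  g <- lift_to_genome(list(cigar = "110M", ref_start = 0L, score = 220),
                      lsrs)
  expect_equal(g$pos, 100L)
  expect_equal(g$cigar, "50M150N60M")

  g2 <- lift_to_genome(list(cigar = "30M", ref_start = 5L, score = 60), lsrs)
  expect_equal(g2$pos, 105L)
  expect_equal(g2$cigar, "30M")                    # inside one segment: no N

  ## a deletion run next to the junction is absorbed into the intron
  g3 <- lift_to_genome(list(cigar = "40M10D60M", ref_start = 0L, score = 0),
                       lsrs)
  expect_equal(g3$cigar, "40M160N60M")

  ## query-consuming ops survive lifting unchanged
  g4 <- lift_to_genome(list(cigar = "40M3I57M2D8M", ref_start = 0L,
                            score = 0), lsrs)
  co <- cigar_ops(g4$cigar)
  expect_equal(sum(co$len[co$op %in% c("M", "I", "S")]), 40 + 3 + 57 + 8)
})

test_that("select_primary orders candidates and assigns the stated MAPQ", {
  cands <- data.frame(score = c(150, 200), chrom = "c1", pos = c(5L, 1L),
                      strand = "+", cigar = "10M")
  out <- select_primary(cands)
  expect_equal(out$score[1], 200)
  expect_true(out$is_primary[1])
  expect_equal(out$mapq[1], 30L)                   # floor(40*50/200)+20

  one <- select_primary(cands[1, , drop = FALSE])
  expect_equal(one$mapq, 60L)

  tie <- data.frame(score = c(200, 200), chrom = "c1", pos = c(900L, 100L),
                    strand = "+", cigar = "10M")
  out2 <- select_primary(tie)
  expect_equal(out2$pos[1], 100L)                  # leftmost wins the tie
  expect_equal(out2$mapq[1], 0L)
})

test_that("polish_junctions restores a shifted junction using splice signals", {
  exA <- random_dna(60, 373); exB <- random_dna(60, 379)
  intr <- paste0("GT", random_dna(196, 383), "AG")
  ref <- c(c1 = paste0(random_dna(20, 389), exA, intr, exB,
                       random_dna(20, 397)))
  query <- paste0(exA, exB)
  ## junction deliberately misplaced 4 bp into the intron
  bad <- paste0(64L, "M", 200L, "N", 56L, "M")
  pol <- polish_junctions(20L, bad, query, ref[[1]])
  expect_equal(pol$cigar, "60M200N60M")
})
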