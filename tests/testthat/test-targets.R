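wc21 <- function() rep("WC", 21)

test_that("penalty scoring follows the position-dependent rules", {
  expect_equal(score_alignment(wc21())$score, 0)

  gu18 <- wc21(); gu18[18] <- "GU"
  expect_equal(score_alignment(gu18)$score, 0.5)

  mm5 <- wc21(); mm5[5] <- "mismatch"
  expect_equal(score_alignment(mm5)$score, 2)

  mm16 <- wc21(); mm16[16] <- "mismatch"
  expect_equal(score_alignment(mm16)$score, 1)

  # doubling region is exactly [2, 13]
  m13 <- wc21(); m13[13] <- "mismatch"
  m14 <- wc21(); m14[14] <- "mismatch"
  expect_equal(score_alignment(m13)$score, 2)
  expect_equal(score_alignment(m14)$score, 1)
  g2 <- wc21(); g2[2] <- "GU"
  expect_equal(score_alignment(g2)$score, 1)

  # position 1 is single-weighted
  p1 <- wc21(); p1[1] <- "mismatch"
  expect_equal(score_alignment(p1)$score, 1)

  # bulges and gaps carry +1 at their position weight
  b7 <- wc21(); b7[7] <- "target_bulge"
  expect_equal(score_alignment(b7)$score, 2)
  g15 <- wc21(); g15[15] <- "mirna_gap"
  expect_equal(score_alignment(g15)$score, 1)

  two <- wc21(); two[c(5, 9)] <- c("target_bulge", "mirna_gap")
  expect_error(score_alignment(two), "at most one")
  expect_error(score_alignment(c("WC", "XX")), "invalid pairing state")
})

test_that("adding a lesion never decreases the score", {
  set.seed(421)
  for (i in 1:100) {
    st <- sample(c("WC", "GU", "mismatch"), 21, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
    base <- score_alignment(st)$score
    p <- sample(which(st == "WC"), 1)
    st2 <- st; st2[p] <- sample(c("GU", "mismatch"), 1)
    expect_gte(score_alignment(st2)$score, base)
  }
})

test_that("align_site finds the optimum over admissible alignments", {
  m <- "TGGAGCTCCCTTCACTCCAAT"
  site0 <- revcomp(m)
  al <- align_site(m, site0)
  expect_equal(al$score, 0)
  expect_true(all(al$pairing == "WC"))

  # one inserted nt opposite the undoubled 3' half scores 1 with a bulge
  ins <- paste0(substr(site0, 1, 6), "A", substr(site0, 7, 21))
  al2 <- align_site(m, ins)
  expect_equal(al2$score, 1)
  expect_equal(sum(al2$pairing == "target_bulge"), 1)

  # window shorter by one forces exactly one miRNA gap
  del <- paste0(substr(site0, 1, 10), substr(site0, 12, 21))
  al3 <- align_site(m, del)
  expect_equal(sum(al3$pairing == "mirna_gap"), 1)

  expect_error(align_site(m, substr(site0, 1, 18)), "within 1 nt")
})

test_that("align_site minimum equals exhaustive enumeration on random pairs", {
  set.seed(422)
  for (i in 1:500) {
    n <- sample(20:22, 1)
    m <- random_dna_str(n)
    w <- sample(c(n - 1, n, n + 1), 1)
    # half the time, perturb the true complement for near-miss structure
    window <- if (i %% 2 == 0) {
      random_dna_str(w)
    } else {
      s <- revcomp(m)
      s <- strsplit(s, "")[[1]]
      for (j in sample(n, 3)) s[j] <- sample(c("A", "C", "G", "T"), 1)
      paste(head(s, w), collapse = "")
    }
    expect_equal(align_site(m, window)$score, oracle_align_min(m, window),
                 info = paste(m, window))
  }
})

test_that("transcriptome scan retains sites by threshold with exactness at 6", {
  set.seed(423)
  m <- paste0("T", random_dna_str(20))
  scores <- c(0, 0.5, 1, 2, 3, 4, 5, 5.5, 6, 6.5, 7, 10)
  planted <- vapply(scores, function(sc) design_site(m, sc), character(1))
  tx <- setNames(
    vapply(planted, function(s) {
      paste0(random_dna_str(40), chartr("U", "T", s), random_dna_str(40))
    }, character(1)),
    paste0("tx", seq_along(scores)))
  pred <- scan_transcriptome(m, tx, max_score = 6, hc_score = 5)
  got <- setNames(rep(NA_real_, length(scores)), names(tx))
  got[pred$transcript] <- pred$score
  expect_equal(unname(got[paste0("tx", which(scores <= 6))]),
               scores[scores <= 6])
  expect_true(all(is.na(got[paste0("tx", which(scores > 6))])))
  expect_equal(pred$high_confidence, pred$score <= 5)
})

test_that("a score-0 site is found exactly once with canonical cleavage", {
  set.seed(424)
  m <- random_dna_str(21)
  site <- revcomp(m)
  tx <- setNames(paste0(random_dna_str(100), site, random_dna_str(100)), "t")
  pred <- scan_transcriptome(m, tx)
  expect_equal(nrow(pred), 1)
  expect_equal(pred$start, 100L)
  expect_equal(pred$score, 0)
  # bond between the nucleotides paired to miRNA positions 10 and 11:
  # offsets 110 | 111
  expect_equal(pred$cleavage, 111L)
})

test_that("random transcripts yield no hits at maximum stringency", {
  set.seed(425)
  m <- random_dna_str(21)
  tx <- setNames(replicate(3, random_dna_str(1000)), paste0("r", 1:3))
  pred <- scan_transcriptome(m, tx, max_score = 0)
  expect_equal(nrow(pred), 0)
  expect_equal(nrow(scan_transcriptome(m, character(0))), 0)
})

test_that("compiled window scan matches the R alignment on random windows", {
  set.seed(426)
  m <- random_dna_str(21)
  tx <- chartr("T", "U", paste0(random_dna_str(150),
                                chartr("U", "T", design_site(m, 2)),
                                random_dna_str(150)))
  hits <- ethysmall:::.scan_windows(chartr("T", "U", m), tx, 100)
  for (k in sample(nrow(hits), 40)) {
    s0 <- hits$start[k]; w <- hits$width[k]
    expect_equal(hits$score[k],
                 align_site(m, substr(tx, s0 + 1, s0 + w))$score)
  }
})

test_that("cleavage position tracks the alignment and flags bulged sites", {
  # gapless: cleavage offset is independent of mismatch content
  set.seed(427)
  m <- random_dna_str(21)
  site_mm <- design_site(m, 3)
  tx <- setNames(paste0(random_dna_str(50), chartr("U", "T", site_mm),
                        random_dna_str(50)), "t")
  pred <- scan_transcriptome(m, tx)
  expect_equal(pred$cleavage, 61L)

  # a bulge at position 10 is flagged to the nearest paired bond
  st <- rep("WC", 21); st[10] <- "target_bulge"
  cl <- ethysmall:::cleavage_from_alignment(0, 22, st)
  expect_true(attr(cl, "flagged"))
})

test_that("RACE fractions are exact", {
  expect_equal(race_fraction(c(rep(111, 5), rep(108, 10)), 111), 1 / 3,
               tolerance = 1e-9)
  expect_equal(race_fraction(rep(42, 7), 42), 1)
  expect_equal(race_fraction(c(1, 2, 3), 9), 0)
  expect_error(race_fraction(integer(0), 1), "no observed")
})
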