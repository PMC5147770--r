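test_that("FPKM follows count * 1e9 / (length * total)", {
  counts <- tibble::tibble(feature = c("g1", "g2"), s1 = c(200L, 0L))
  out <- compute_fpkm(counts, c(g1 = 2000, g2 = 500), totals = c(s1 = 1e6))
  expect_equal(out$s1, c(100, 0))
  out2 <- compute_fpkm(counts, c(g1 = 2000, g2 = 500), totals = c(s1 = 2e6))
  expect_equal(out2$s1[1], 50)
  expect_error(compute_fpkm(counts, c(g1 = 0, g2 = 1)), "length")
})

test_that("replicate correlation filters at FPKM > 0.5 in both replicates", {
  set.seed(431)
  base <- exp(rnorm(200, 3, 1))
  fpkm <- tibble::tibble(feature = paste0("g", 1:200),
                         a_1 = base, a_2 = base)
  rc <- replicate_correlation(fpkm)
  expect_equal(rc$r, 1)

  # a gene at exactly 0.5 in one replicate is excluded
  fpkm2 <- tibble::tibble(feature = c("g1", "g2", "g3", "g4"),
                          a_1 = c(0.5, 2, 3, 4), a_2 = c(5, 2, 3, 4))
  rc2 <- replicate_correlation(fpkm2)
  expect_equal(rc2$n_genes, 3)

  # independent replicates decorrelate
  fpkm3 <- tibble::tibble(feature = paste0("g", 1:1000),
                          b_1 = exp(rnorm(1000, 2, 1)),
                          b_2 = exp(rnorm(1000, 2, 1)))
  rc3 <- replicate_correlation(fpkm3)
  expect_lt(abs(rc3$r), 0.2)

  expect_warning(
    replicate_correlation(tibble::tibble(feature = c("g1", "g2"),
                                         c_1 = c(1, 0.1), c_2 = c(1, 0.1))),
    "fewer than 3")
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.005, 0.02, 0.03)), c(0.015, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(432)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("the pooled exact test matches a hypergeometric-sum oracle", {
  set.seed(433)
  cases <- rbind(
    c(100, 1e6, 300, 1e6),
    c(0, 1e5, 50, 1e5),
    c(5, 1e4, 5, 1e4),
    matrix(c(rpois(20, 80), rep(5e5, 20), rpois(20, 120), rep(7e5, 20)),
           ncol = 4))
  for (r in seq_len(nrow(cases))) {
    got <- ethysmall:::exact_count_test(cases[r, 1], cases[r, 2],
                                        cases[r, 3], cases[r, 4])
    expect_equal(got, oracle_exact_p(cases[r, 1], cases[r, 2],
                                     cases[r, 3], cases[r, 4]),
                 tolerance = 1e-6)
  }
})

test_that("miRNA differential calls combine fold-change and BH thresholds", {
  counts <- tibble::tibble(
    feature = c("called", "small_fc", "flat"),
    a1 = c(100L, 100L, 200L), a2 = c(100L, 100L, 200L),
    b1 = c(300L, 130L, 200L), b2 = c(300L, 130L, 200L))
  totals <- c(a1 = 1e6, a2 = 1e6, b1 = 1e6, b2 = 1e6)
  res <- diff_mirna(counts, list(cond1 = c("b1", "b2"),
                                 cond2 = c("a1", "a2")), totals = totals)
  expect_equal(res$direction[res$feature == "called"], "up")
  expect_equal(res$fold_change[res$feature == "called"], 600.5 / 200.5,
               tolerance = 1e-9)
  # 1.3x is below the 1.5 threshold regardless of p
  expect_equal(res$direction[res$feature == "small_fc"], "ns")
  expect_equal(res$direction[res$feature == "flat"], "ns")
  expect_true(all(res$padj >= res$p))
  expect_error(diff_mirna(counts, list(cond1 = "a1", cond2 = "b1"),
                          totals = c(a1 = 0, b1 = 1)), "zero")
})

test_that("swapping condition labels flips directions only", {
  set.seed(434)
  counts <- tibble::tibble(feature = paste0("f", 1:50),
                           a1 = rpois(50, 100), a2 = rpois(50, 100),
                           b1 = rpois(50, c(rep(300, 10), rep(100, 40))),
                           b2 = rpois(50, c(rep(300, 10), rep(100, 40))))
  totals <- c(a1 = 1e6, a2 = 1e6, b1 = 1e6, b2 = 1e6)
  fwd <- diff_mirna(counts, list(cond1 = c("b1", "b2"),
                                 cond2 = c("a1", "a2")), totals = totals)
  rev <- diff_mirna(counts, list(cond1 = c("a1", "a2"),
                                 cond2 = c("b1", "b2")), totals = totals)
  expect_equal(fwd$p, rev$p)
  flip <- c(up = "down", down = "up", ns = "ns")
  expect_equal(rev$direction, unname(flip[fwd$direction]))
})

test_that("gene differential expression applies the RPKM floor before testing", {
  len <- c(hi = 1000, lo = 1000)
  counts <- tibble::tibble(
    feature = c("hi", "lo"),
    a1 = c(4000L, 0L), a2 = c(4000L, 0L),
    b1 = c(1000L, 0L), b2 = c(1000L, 1L))
  totals <- c(a1 = 1e6, a2 = 1e6, b1 = 1e6, b2 = 1e6)
  res <- diff_gene(counts, len, list(cond1 = c("a1", "a2"),
                                     cond2 = c("b1", "b2")),
                   totals = totals)
  # 'lo' never exceeds 1 RPKM: not tested at all
  expect_false("lo" %in% res$feature)
  expect_equal(res$direction[res$feature == "hi"], "up")
  expect_equal(attr(res, "unit"), "FPKM")
})

test_that("a fold change exactly at the threshold is called (inclusive)", {
  counts <- tibble::tibble(feature = "m", a1 = 1000L, b1 = 1000L)
  # equal counts, totals in ratio 1.5: fold change is exactly 1.5
  totals <- c(a1 = 1e6, b1 = 1.5e6)
  res <- diff_mirna(counts, list(cond1 = "a1", cond2 = "b1"),
                    totals = totals)
  expect_equal(res$fold_change, 1.5)
  expect_equal(res$direction, "up")
  res2 <- diff_mirna(counts, list(cond1 = "a1", cond2 = "b1"),
                     min_fc = 1.5 + 1e-9, totals = totals)
  expect_equal(res2$direction, "ns")
})

test_that("tidy and glance summarize differential results", {
  counts <- tibble::tibble(feature = c("x", "y"),
                           a1 = c(10L, 500L), b1 = c(12L, 100L))
  res <- diff_mirna(counts, list(cond1 = "a1", cond2 = "b1"),
                    totals = c(a1 = 1e5, b1 = 1e5))
  td <- tidy(res)
  expect_false(inherits(td, "ethy_diff"))
  expect_equal(nrow(td), 2)
  gl <- glance(res)
  expect_equal(gl$n_tested, 2)
  expect_equal(gl$n_up + gl$n_down + gl$n_ns, 2)
})
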