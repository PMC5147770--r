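# a compact planted genome for direct discovery-stage tests
planted_genome <- function(seed = 101, k = 0) {
  set.seed(seed)
  hp <- make_hairpin(21, 15, k = k)
  genome <- c(chr1 = paste0(random_dna_str(400), hp$seq, random_dna_str(400)))
  list(genome = genome, mature = hp$mature, star = hp$star,
       mature_start = 400L)  # 0-based
}

test_that("seeding uses pooled counts with an inclusive threshold", {
  tags <- tibble::tibble(tag = c("A", "B", "C"),
                         l1 = c(20L, 30L, 31L), l2 = c(29L, 20L, 20L),
                         total = c(49L, 50L, 51L))
  expect_equal(seed_candidates(tags, 50)$tag, c("B", "C"))
  expect_equal(nrow(seed_candidates(tags, 60)), 0)
  expect_equal(nrow(seed_candidates(tags, 0)), 3)
})

test_that("window enumeration steps 100-500 nt and clips at chromosome ends", {
  hit <- tibble::tibble(chrom = "chr1", start = 1000L, strand = "+")
  w <- enumerate_windows(hit, 21, 5000)
  expect_equal(nrow(w), 5)
  expect_equal(w$extension, seq(100, 500, 100))
  expect_equal(w$end - w$start, 21 + 2 * seq(100, 500, 100))
  expect_equal(w$mature_offset, seq(100, 500, 100))

  near <- tibble::tibble(chrom = "chr1", start = 50L, strand = "+")
  wn <- enumerate_windows(near, 21, 5000)
  expect_true(all(wn$start == 0))
  expect_equal(wn$mature_offset, rep(50L, 5))

  # minus-strand offsets count from the window's 3' (right) genome end
  minus <- tibble::tibble(chrom = "chr1", start = 4950L, strand = "-")
  wm <- enumerate_windows(minus, 21, 5000)
  expect_true(all(wm$end == 5000))
  expect_equal(wm$mature_offset, rep(29L, 5))
})

test_that("a planted hairpin is accepted at the smallest extension", {
  pg <- planted_genome(102, k = 0)
  hit <- tibble::tibble(chrom = "chr1", start = pg$mature_start, strand = "+")
  wins <- enumerate_windows(hit, 21, nchar(pg$genome[[1]]))
  ev <- evaluate_precursor(wins, 21, pg$genome)
  expect_true(ev$accepted)
  expect_equal(ev$window$extension, 100)
  expect_equal(ev$duplex$mismatch_ratio, 0)

  ref <- refine_with_margins(ev, pg$genome)
  expect_true(ref$accepted)
  expect_equal(ref$mature, pg$mature)
  expect_equal(ref$arm, "5p")
  # refined precursor contains the planted mature interval
  expect_lte(ref$precursor$start, pg$mature_start)
  expect_gte(ref$precursor$end, pg$mature_start + 21)
})

test_that("a seed in unstructured background is rejected", {
  set.seed(103)
  genome <- c(chr1 = random_dna_str(900))
  tag <- substr(genome[[1]], 441, 461)
  hit <- tibble::tibble(chrom = "chr1", start = 440L, strand = "+")
  wins <- enumerate_windows(hit, 21, 900)
  ev <- evaluate_precursor(wins, 21, genome)
  ok <- !ev$accepted || !refine_with_margins(ev, genome)$accepted
  expect_true(ok)
})

test_that("tandem hairpins in the refined interval are rejected as multi-stem", {
  set.seed(104)
  hp1 <- make_hairpin(21, 15, k = 0)
  hp2 <- make_hairpin(21, 15, k = 0)
  genome <- c(chr1 = paste0(random_dna_str(300), hp1$seq, strrep("A", 6),
                            hp2$seq, random_dna_str(300)))
  f <- fold(substr(genome[[1]], 301, 300 + 57 + 6 + 57), engine = "vienna")
  expect_false(is_single_hairpin(f))
})

test_that("duplex alignment measures arm complementarity independently", {
  set.seed(105)
  hp <- make_hairpin(21, 15, k = 2)
  ds <- duplex_align(hp$mature, hp$star)
  expect_equal(ds$unpaired_mature, 2)
  expect_equal(ds$asymmetry, 0)

  # random arms barely pair
  ds2 <- duplex_align(random_dna_str(21), random_dna_str(21))
  expect_gt(ds2$unpaired_mature, 5)
})

test_that("family grouping joins by sequence distance <= 2 or locus overlap", {
  set.seed(108)
  base <- random_dna_str(21)
  two_sub <- base
  substr(two_sub, 3, 3) <- if (substr(base, 3, 3) == "A") "C" else "A"
  substr(two_sub, 9, 9) <- if (substr(base, 9, 9) == "G") "T" else "G"
  three_sub <- base
  for (p in c(15, 17, 19)) {
    substr(three_sub, p, p) <- if (substr(base, p, p) == "C") "G" else "C"
  }
  cand <- tibble::tibble(
    mature = c(base, base, two_sub, three_sub, random_dna_str(21)),
    chrom = "chr1",
    start = c(0L, 1000L, 2000L, 3000L, 3010L),
    end = c(90L, 1090L, 2090L, 3090L, 3100L),
    strand = "+")
  fam <- group_families(cand)
  # identical matures at different loci: one family
  expect_equal(fam$family[1], fam$family[2])
  # two substitutions: same family; three: different unless loci overlap
  expect_equal(fam$family[1], fam$family[3])
  # rows 4 and 5 overlap in coordinates: same family despite dissimilarity
  expect_equal(fam$family[4], fam$family[5])
  expect_false(fam$family[1] == fam$family[4])
  # family id is the lexicographically smallest member
  expect_equal(fam$family[1], min(c(base, two_sub)))
})

test_that("known-miRNA matching labels whole families", {
  set.seed(106)
  a <- random_dna_str(21)
  b <- a; substr(b, 5, 5) <- if (substr(a, 5, 5) == "A") "G" else "A"
  far <- random_dna_str(21)
  cand <- tibble::tibble(mature = c(a, b, far), chrom = "chr1",
                         start = c(0L, 500L, 5000L),
                         end = c(90L, 590L, 5090L), strand = "+")
  cand <- group_families(cand)
  known <- c(mirX = a)
  out <- match_known(cand, known)
  expect_equal(out$known_match[1], "mirX")
  # b is one substitution from a: same family, inherits the label
  expect_equal(out$known_match[2], "mirX")
  expect_true(out$direct_match[2])  # also within 2 mismatches directly
  expect_true(is.na(out$known_match[3]))
  expect_true(out$novel[3])

  # three mismatches -> novel
  c3 <- a
  for (p in c(2, 8, 14)) {
    substr(c3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(a, p, p))[1]
  }
  cand3 <- group_families(tibble::tibble(mature = c3, chrom = "chr1",
                                         start = 9000L, end = 9090L,
                                         strand = "+"))
  out3 <- match_known(cand3, known)
  expect_true(is.na(out3$known_match))

  # empty known set: everything novel
  out0 <- match_known(cand, character(0))
  expect_true(all(out0$novel))
})

test_that("support threshold behavior is exact at the 50-read boundary", {
  pg <- planted_genome(107, k = 0)
  tags <- tibble::tibble(tag = pg$mature, l1 = 49L, total = 49L)
  expect_equal(nrow(seed_candidates(tags, 50)), 0)
  tags$l1 <- 50L; tags$total <- 50L
  expect_equal(nrow(seed_candidates(tags, 50)), 1)
})
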