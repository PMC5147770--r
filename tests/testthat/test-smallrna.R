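read_tbl <- function(seqs, quals = NULL) {
  quals <- quals %||% strrep("I", nchar(seqs))
  tibble::tibble(id = paste0("r", seq_along(seqs)), sequence = seqs,
                 quality = quals)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("quality filter keeps high-quality N-free reads in order", {
  rd <- read_tbl(c("ACGTACGT", "ACGNACGT", "ACGTACGA"),
                 c(strrep("I", 8), strrep("I", 8), strrep("#", 8)))
  out <- filter_quality(rd, min_mean_q = 20)
  expect_equal(out$sequence, "ACGTACGT")   # N removed, low-Q removed
  expect_equal(filter_quality(rd[0, ]), rd[0, ])
  # boundary: mean exactly at threshold is kept
  q20 <- intToUtf8(33 + 20)
  rd2 <- read_tbl("ACGT", strrep(q20, 4))
  expect_equal(nrow(filter_quality(rd2, 20)), 1)
  # malformed record named in the error
  bad <- tibble::tibble(id = "oops", sequence = "ACGT", quality = "II")
  expect_error(filter_quality(bad), "oops")
})

test_that("adapter trimming removes the leftmost adapter hit and short leftovers", {
  adapter <- "AGATCGGAAGAGC"
  insert <- "ACGTACGTACGTACGTACGT"
  rd <- read_tbl(c(
    paste0(insert, adapter),            # full adapter
    insert,                             # no adapter
    paste0(adapter, "ACGT"),            # pure adapter start -> discarded
    paste0(insert, substr(adapter, 1, 8))  # 8-nt adapter prefix
  ))
  out <- trim_adapter(rd, adapter, min_overlap = 8)
  expect_equal(out$sequence, c(insert, insert, insert))
  expect_equal(nchar(out$quality), nchar(out$sequence))
})

test_that("tag collapsing conserves counts and splits libraries", {
  rds <- list(
    lib1 = read_tbl(c("AAAA", "AAAA", "CCCC")),
    lib2 = read_tbl(c("AAAA", "GGGG", "GGGG", "TTTT")),
    lib3 = read_tbl(c("CCCC", "CCCC", "TTTT"))
  )
  tags <- collapse_tags(rds)
  expect_equal(sum(tags$total), 10)
  expect_equal(tags$lib1[tags$tag == "AAAA"], 2)
  expect_equal(tags$lib2[tags$tag == "AAAA"], 1)
  expect_equal(sort(tags$tag), sort(unique(unlist(lapply(rds, `[[`, "sequence")))))
  expect_equal(nrow(collapse_tags(list(l = read_tbl(character(0))))), 0)
})

test_that("exact mapping reports all hits on both strands", {
  genome <- c(chr1 = "ACGTACGTAAAT")
  hits <- map_exact(tibble::tibble(tag = "CGTA"), genome)
  # deterministic order: (chromosome, start, strand)
  expect_equal(hits$start, c(1L, 3L, 5L))
  expect_equal(hits$strand, c("+", "-", "+"))

  # tag longer than the genome is unmapped
  h2 <- map_exact(tibble::tibble(tag = strrep("A", 20)), genome)
  expect_equal(nrow(h2), 0)
  expect_equal(attr(h2, "unmapped"), strrep("A", 20))

  # tag equal to the genome
  h3 <- map_exact(tibble::tibble(tag = "ACGTACGTAAAT"), genome)
  expect_equal(h3$start, 0L)
  expect_equal(h3$strand, "+")
})

test_that("exact mapping agrees with a sliding-window oracle on random genomes", {
  set.seed(411)
  for (i in 1:20) {
    genome <- c(chrA = random_dna_str(sample(200:800, 1)))
    tags <- tibble::tibble(tag = c(
      replicate(5, random_dna_str(sample(4:8, 1))),
      substr(genome[[1]], 50, 70)  # a guaranteed hit
    ))
    got <- map_exact(tags, genome)
    for (tg in tags$tag) {
      exp <- oracle_map(tg, genome[[1]])
      sub <- got[got$tag == tg, ]
      expect_equal(nrow(sub), nrow(exp), info = tg)
      if (nrow(exp) > 0) {
        o <- order(exp$start, exp$strand)
        expect_equal(sub$start, exp$start[o])
        expect_equal(sub$strand, exp$strand[o])
      }
    }
  }
})

test_that("structural-RNA exclusion removes any tag overlapping by >= 1 nt", {
  genome <- c(chr1 = paste0(strrep("A", 50), "CCCCGGGGCC", strrep("A", 50)))
  tags <- tibble::tibble(tag = c("CCCCGGGGCC", "AAAAAAAACC", "AAAAAAAAAA"),
                         l1 = c(5L, 5L, 5L), total = c(5L, 5L, 5L))
  hits <- map_exact(tags, genome)
  ann <- tibble::tibble(chrom = "chr1", start = 50L, end = 60L,
                        class = "rRNA")
  kept <- exclude_structural(tags, hits, ann)
  # tag inside the rRNA and the 2-nt-overlap tag go; the pure-A tag has a
  # hit adjacent (0 overlap) at 40..50 among others, but also hits inside?
  expect_false("CCCCGGGGCC" %in% kept$tag)
  expect_false("AAAAAAAACC" %in% kept$tag)
  ann2 <- tibble::tibble(chrom = "chr1", start = 0L, end = 40L,
                         class = "tRNA")
  kept2 <- exclude_structural(tags, hits, ann2)
  expect_false("AAAAAAAAAA" %in% kept2$tag)  # overlaps 0..40

  expect_warning(
    exclude_structural(tags, hits,
                       tibble::tibble(chrom = "chr1", start = 0L, end = 5L,
                                      class = "mystery")),
    "unknown annotation classes")
})

test_that("adjacent (zero-overlap) tags survive structural exclusion", {
  genome <- c(chr1 = paste0("TTTTGGGGTT", "CCCCAACCCA"))
  tags <- tibble::tibble(tag = "CCCCAACCCA", l1 = 1L, total = 1L)
  hits <- map_exact(tags, genome)
  ann <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L, class = "snRNA")
  expect_true("CCCCAACCCA" %in% exclude_structural(tags, hits, ann)$tag)
})

test_that("length filter keeps the inclusive 18-28 range", {
  tags <- tibble::tibble(tag = vapply(c(17, 18, 28, 29), random_dna_str,
                                      character(1)))
  out <- length_filter(tags)
  expect_equal(sort(nchar(out$tag)), c(18, 28))
  expect_equal(nrow(length_filter(tags[0, ])), 0)
  only21 <- length_filter(tibble::tibble(tag = vapply(c(20, 21, 22),
                                                      random_dna_str,
                                                      character(1))),
                          21, 21)
  expect_equal(nchar(only21$tag), 21)
  expect_error(length_filter(tags, 20, 18), "min_len")
})

test_that("CP10M normalization follows count * 1e7 / mapped", {
  tags <- tibble::tibble(tag = c("A1", "A2", "A3"),
                         libX = c(50L, 0L, 5000000L))
  out <- normalize_cp10m(tags, c(libX = 5e6))
  expect_equal(out$libX, c(100, 0, 1e7))
  expect_error(normalize_cp10m(tags, c(libX = 0)), "zero")
})

test_that("length/5'-nucleotide profile conserves totals and zero-fills", {
  cp <- tibble::tibble(tag = c("TACGTACGTACGTACGTACGT",  # 21 nt, U start
                               "AACGTACGTACGTACGTAAGGCAT"),  # 24 nt, A
                       lib1 = c(100, 50), lib2 = c(0, 10))
  prof <- length_5p_profile(cp)
  expect_equal(sum(prof$cp10m), sum(cp$lib1) + sum(cp$lib2))
  one <- prof[prof$library == "lib1" & prof$length == 21, ]
  expect_equal(one$cp10m[one$first_nt == "U"], 100)
  expect_equal(sum(one$cp10m), 100)
  empty <- length_5p_profile(cp[0, ])
  expect_true(all(empty$cp10m == 0))
  expect_equal(nrow(empty), 2 * 11 * 4)
})

test_that("filters are idempotent and monotone", {
  set.seed(412)
  tags <- tibble::tibble(tag = replicate(30, random_dna_str(sample(15:32, 1))),
                         l1 = 1L, total = 1L)
  f1 <- length_filter(tags)
  expect_equal(length_filter(f1), f1)
  expect_lte(nrow(f1), nrow(tags))
})
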