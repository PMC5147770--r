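# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: naive recursion, sliding windows, direct sums.

# exhaustive maximum base-pair count over nested structures (naive
# recursion, no DP table reuse across calls)
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (ok(ch[i], ch[k])) {
        v <- 1L + rec(i + 1, k - 1) + if (k < j) rec(k + 1, j) else 0L
        if (v > best) best <- v
      }
    }
    best
  }
  if (length(ch) < min_loop + 2) return(0L)
  rec(1L, length(ch))
}

# sliding-window exact matching on both strands
oracle_map <- function(tag, genome_seq) {
  n <- nchar(tag); L <- nchar(genome_seq)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  hits <- list()
  if (n <= L) {
    for (s in 0:(L - n)) {
      w <- substr(genome_seq, s + 1, s + n)
      if (w == tag) hits[[length(hits) + 1]] <- c(s, "+")
      if (w == rc) hits[[length(hits) + 1]] <- c(s, "-")
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), strand = character()))
  }
  data.frame(start = as.integer(sapply(hits, `[`, 1)),
             strand = sapply(hits, `[`, 2))
}

# Benjamini-Hochberg step-up written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# two-sided conditional exact p for a 2x2 by direct hypergeometric summation
oracle_exact_p <- function(k1, t1, k2, t2) {
  total <- k1 + k2
  support <- max(0, total - t2):min(total, t1)
  dens <- dhyper(support, t1, t2, total)
  obs <- dhyper(k1, t1, t2, total)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# minimum penalty over all admissible miRNA:window alignments, enumerated
# directly from the scoring rules (independent of align_site's indexing)
oracle_align_min <- function(mirna, window) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  s <- strsplit(chartr("T", "U", toupper(window)), "")[[1]]
  n <- length(m); w <- length(s)
  pen1 <- function(a, b) {
    pr <- paste0(a, b)
    if (pr %in% c("AU", "UA", "GC", "CG")) return(0)
    if (pr %in% c("GU", "UG")) return(0.5)
    1
  }
  wt <- function(p) if (p >= 2 && p <= 13) 2 else 1
  score_of <- function(site_index_of) {
    # site_index_of: function p -> site index or NA (lesion at p)
    tot <- 0
    for (p in seq_len(n)) {
      j <- site_index_of(p)
      tot <- tot + wt(p) * if (is.na(j)) 1 else pen1(m[p], s[j])
    }
    tot
  }
  if (w == n) {
    return(score_of(function(p) n - p + 1))
  }
  best <- Inf
  for (b in seq_len(n)) {
    f <- if (w == n + 1) {
      function(p) if (p == b) NA_integer_ else if (p < b) w - p + 1 else w - p
    } else {
      function(p) if (p == b) NA_integer_ else if (p < b) w - p + 1
        else w - p + 2
    }
    best <- min(best, score_of(f))
  }
  best
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a clean planted hairpin sequence: mature + loop + star with k non-pairing
# substitutions; returns list(seq, mature, star)
make_hairpin <- function(mature_len = 21, loop_len = 15, k = 0) {
  mature <- random_dna_str(mature_len)
  star <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(mature)))
  if (k > 0) {
    pos <- sample.int(mature_len, k)
    st <- strsplit(star, "")[[1]]
    mt <- strsplit(chartr("T", "U", mature), "")[[1]]
    bad <- list(A = c("A", "G", "C"), G = c("A", "G"),
                U = c("C", "U"), C = c("A", "C", "U"))
    for (j in pos) {
      partner <- mt[mature_len - j + 1]
      st[j] <- chartr("U", "T", sample(bad[[partner]], 1))
    }
    star <- paste(st, collapse = "")
  }
  list(seq = paste0(mature, random_dna_str(loop_len), star),
       mature = mature, star = star)
}
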