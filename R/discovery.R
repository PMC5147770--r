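#' Seed miRNA candidates by pooled read support
#'
#' Tags whose read count pooled across all libraries reaches `min_reads`
#' become candidate seeds for precursor evaluation.
#'
#' @param tags tag tibble with per-library counts and `total`.
#' @param min_reads pooled-read threshold (default 50, inclusive).
#' @return the seed subset of `tags`.
#' @export
seed_candidates <- function(tags, min_reads = 50) {
  if (!"total" %in% names(tags)) {
    libs <- setdiff(names(tags), "tag")
    tags$total <- rowSums(tags[, libs, drop = FALSE])
  }
  tags[tags$total >= min_reads, , drop = FALSE]
}

#' Candidate precursor windows around a seed hit
#'
#' For one genome hit, windows extend the seed upstream and downstream by
#' 100 to 500 nt in steps of 100, clipped at chromosome ends; ordered by
#' extension.
#'
#' @param hit one row of a hit tibble (`chrom`, `start` 0-based, `strand`).
#' @param seed_length tag length in nt.
#' @param chrom_length length of the hit chromosome.
#' @param extensions extension grid (default `seq(100, 500, 100)`).
#' @return tibble `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `extension`, `mature_offset` (0-based offset of the seed within the
#'   window, on the window's strand orientation).
#' @export
enumerate_windows <- function(hit, seed_length, chrom_length,
                              extensions = seq(100, 500, 100)) {
  purrr::map_dfr(extensions, function(ext) {
    s <- max(0, hit$start - ext)
    e <- min(chrom_length, hit$start + seed_length + ext)
    off <- if (hit$strand == "+") hit$start - s else e - (hit$start + seed_length)
    tibble(chrom = hit$chrom, start = s, end = e, strand = hit$strand,
           extension = ext, mature_offset = off)
  })
}

window_sequence <- function(window, genome) {
  seqc <- substr(genome[[window$chrom]], window$start + 1, window$end)
  if (window$strand == "-") seqc <- revcomp(seqc)
  seqc
}

#' Evaluate precursor windows for one seed
#'
#' Folds each window (smallest extension first), extracts the miRNA/miRNA*
#' duplex at the seed position and accepts the first window whose duplex
#' has a mismatch ratio at or below `max_ratio` and whose star arm does not
#' overlap the mature. Rejection reasons: `no_pairing` (nothing pairs),
#' `ratio_exceeded`, `star_overlap`.
#'
#' @param windows window tibble from [enumerate_windows()].
#' @param seed_length mature length in nt.
#' @param genome named character vector.
#' @param max_ratio duplex mismatch-ratio ceiling (default 0.3, inclusive).
#' @param min_loop fold loop constraint.
#' @param engine fold engine (see [fold()]); default `"vienna"`.
#' @return list with `accepted` (logical), `window`, `fold`, `duplex`,
#'   `reason` (`NA` when accepted).
#' @export
evaluate_precursor <- function(windows, seed_length, genome, max_ratio = 0.3,
                               min_loop = 3, engine = "vienna") {
  reasons <- character(0)
  for (i in seq_len(nrow(windows))) {
    win <- windows[i, ]
    f <- fold(window_sequence(win, genome), min_loop = min_loop,
              engine = engine)
    dx <- extract_duplex(f, win$mature_offset + 1, seed_length)
    if (dx$paired == 0) { reasons <- c(reasons, "no_pairing"); next }
    if (dx$mismatch_ratio > max_ratio) {
      reasons <- c(reasons, "ratio_exceeded"); next
    }
    if (dx$star_start <= dx$mature_end && dx$star_end >= dx$mature_start) {
      reasons <- c(reasons, "star_overlap"); next
    }
    return(list(accepted = TRUE, window = win, fold = f, duplex = dx,
                reason = NA_character_))
  }
  list(accepted = FALSE, window = NULL, fold = NULL, duplex = NULL,
       reason = if (length(reasons) > 0) reasons[length(reasons)]
                else "no_window")
}

#' Align a mature miRNA against its star sequence as a duplex
#'
#' Overlap (free-end-gap) alignment of the mature sequence against the
#' reversed star arm, maximizing pairable columns (Watson-Crick or G:U)
#' with a small gap cost. This measures the miRNA/miRNA* duplex directly —
#' independent of how the precursor fold arranges interior loops — which is
#' what the plant-miRNA annotation criteria describe: end overhangs are
#' free, aligned non-pairable columns are symmetric mismatches, interior
#' gap columns are asymmetric-bulge nucleotides.
#'
#' @param mature,star sequences 5'->3' (as written in the precursor).
#' @return list `paired` (pairable columns), `unpaired_mature`
#'   (mature length minus paired), `asymmetry` (interior gap columns,
#'   either side).
#' @export
duplex_align <- function(mature, star) {
  m <- seq_chars(dna_to_rna(mature))
  s <- rev(seq_chars(dna_to_rna(star)))
  n <- length(m); k <- length(s)
  pairable <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "U") || (a == "U" && b == "G")
  }
  ## a gap must cost more than the one pair it could buy, so isolated
  ## mismatches stay symmetric; a genuine bulge still pays for itself by
  ## restoring the downstream helix
  gap <- -0.6
  S <- matrix(0, n + 1, k + 1)   # free end gaps: first row/col zero
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      diag <- S[i, j] + if (pairable(m[i], s[j])) 1 else 0
      S[i + 1, j + 1] <- max(diag, S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  ## best end on the last row or column (end gaps free)
  ends <- rbind(cbind(n + 1, seq_len(k + 1)), cbind(seq_len(n + 1), k + 1))
  vals <- S[ends]
  e <- ends[which.max(vals), ]
  i <- e[1]; j <- e[2]
  paired <- 0L; gaps_interior <- 0L
  while (i > 1 && j > 1) {
    diagv <- S[i - 1, j - 1] + if (pairable(m[i - 1], s[j - 1])) 1 else 0
    if (abs(S[i, j] - diagv) < 1e-9) {
      if (pairable(m[i - 1], s[j - 1])) paired <- paired + 1L
      i <- i - 1; j <- j - 1
    } else if (abs(S[i, j] - (S[i - 1, j] + gap)) < 1e-9) {
      gaps_interior <- gaps_interior + 1L
      i <- i - 1
    } else {
      gaps_interior <- gaps_interior + 1L
      j <- j - 1
    }
  }
  list(paired = paired, unpaired_mature = n - paired,
       asymmetry = gaps_interior)
}

#' Refold the minimal precursor with margins and apply annotation criteria
#'
#' Re-folds the interval from the outermost of (mature, star) minus
#' `margin` to the outermost end plus `margin`, shrinking the interval and
#' refolding (up to 3 rounds) when the refold relocates the star arm
#' inward — the window-stage fold can scatter a few partners far from the
#' true duplex. The candidate is accepted iff the final refold is a single
#' hairpin, the star does not overlap the mature, and the refold duplex
#' (measured by [duplex_align()] on the extracted arms — robust to the
#' interior-loop rearrangements thermodynamic folds introduce) has at most
#' `max_unpaired` unpaired mature positions and at most `max_asymmetry` nt
#' of asymmetric bulge. Rejection reasons: `multi_stem`, `no_pairing`,
#' `too_many_unpaired`, `asymmetric_bulge`, `star_overlap`.
#'
#' @param accepted result of a successful [evaluate_precursor()].
#' @param genome named character vector.
#' @param margin margin in nt (default 15).
#' @param max_unpaired maximum unpaired mature positions (default 5).
#' @param max_asymmetry maximum nt of asymmetric bulge (default 2).
#' @param min_loop fold loop constraint.
#' @param min_branch_pairs stem-size floor for [is_single_hairpin()].
#' @param engine fold engine (see [fold()]); default `"vienna"`.
#' @return list `accepted`, `reason`, plus on success `precursor`
#'   (tibble `chrom`, `start`, `end`, `strand`, 0-based genome coords of
#'   the refined interval), `mature`, `star` (sequences, 5'->3' as written
#'   in the precursor), `duplex` (refold duplex row), `duplex_stats`
#'   (from [duplex_align()]), `arm` (`"5p"`/`"3p"`).
#' @export
refine_with_margins <- function(accepted, genome, margin = 15,
                                max_unpaired = 5, max_asymmetry = 2,
                                min_loop = 3, min_branch_pairs = 8,
                                engine = "vienna") {
  win <- accepted$window
  dx <- accepted$duplex
  seed_length <- dx$mature_end - dx$mature_start + 1
  reject <- function(reason) list(accepted = FALSE, reason = reason)

  ## mature interval in genome coords (0-based half-open), fixed throughout
  to_genome <- function(interval, a, b) {
    ## local 1-based inclusive [a, b] inside interval -> genome half-open
    if (interval$strand == "+") {
      c(interval$start + a - 1, interval$start + b)
    } else {
      c(interval$end - b, interval$end - a + 1)
    }
  }
  g_mature <- to_genome(tibble(chrom = win$chrom, start = win$start,
                               end = win$end, strand = win$strand),
                        dx$mature_start, dx$mature_end)

  current <- tibble(chrom = win$chrom, start = win$start, end = win$end,
                    strand = win$strand)
  star_lo <- dx$star_start; star_hi <- dx$star_end
  mature_lo <- dx$mature_start
  f <- NULL; dx2 <- NULL; seqc <- NULL
  for (iter in 1:3) {
    lo <- min(mature_lo, star_lo)
    hi <- max(mature_lo + seed_length - 1, star_hi)
    L <- current$end - current$start
    lo2 <- max(1, lo - margin); hi2 <- min(L, hi + margin)
    g <- to_genome(current, lo2, hi2)
    refined <- tibble(chrom = current$chrom, start = g[1], end = g[2],
                      strand = current$strand)
    seqc <- window_sequence(refined, genome)
    f <- fold(seqc, min_loop = min_loop, engine = engine)
    ## mature local position inside the refined interval
    mature_lo <- if (refined$strand == "+") {
      g_mature[1] - refined$start + 1
    } else {
      refined$end - g_mature[2] + 1
    }
    dx2 <- extract_duplex(f, mature_lo, seed_length)
    if (dx2$paired == 0) return(reject("no_pairing"))
    current <- refined
    new_span <- max(dx2$mature_end, dx2$star_end) -
      min(dx2$mature_start, dx2$star_start) + 1
    if (new_span >= (hi - lo + 1) || iter == 3) break
    star_lo <- dx2$star_start; star_hi <- dx2$star_end
  }
  if (!is_single_hairpin(f, min_branch_pairs)) return(reject("multi_stem"))
  if (dx2$star_start <= dx2$mature_end && dx2$star_end >= dx2$mature_start) {
    return(reject("star_overlap"))
  }
  mature_seq <- substr(seqc, dx2$mature_start, dx2$mature_end)
  star_seq <- substr(seqc, dx2$star_start, dx2$star_end)
  ds <- duplex_align(mature_seq, star_seq)
  if (ds$unpaired_mature > max_unpaired) return(reject("too_many_unpaired"))
  if (ds$asymmetry > max_asymmetry) return(reject("asymmetric_bulge"))
  arm <- if (dx2$mature_start < dx2$star_start) "5p" else "3p"
  sg <- to_genome(current, dx2$star_start, dx2$star_end)
  list(accepted = TRUE, reason = NA_character_, precursor = current,
       fold = f, duplex = dx2, duplex_stats = ds, mature = mature_seq,
       star = star_seq, arm = arm,
       star_interval = tibble(chrom = current$chrom, start = sg[1],
                              end = sg[2], strand = current$strand))
}

#' Group miRNA candidates into families
#'
#' Single-linkage clustering: two candidates join the same family when
#' their mature sequences are within `max_dist` substitutions after
#' end-alignment (length difference counts against the distance) or their
#' precursor intervals overlap. Family ids are the lexicographically
#' smallest mature sequence of the family.
#'
#' @param candidates tibble with `mature`, `chrom`, `start`, `end`,
#'   `strand` (one row per candidate).
#' @param max_dist sequence distance threshold (default 2).
#' @return `candidates` with a `family` column.
#' @export
group_families <- function(candidates, max_dist = 2) {
  n <- nrow(candidates)
  if (n == 0) return(dplyr::mutate(candidates, family = character(0)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      near_seq <- mature_distance(candidates$mature[i],
                                  candidates$mature[j]) <= max_dist
      same_locus <- candidates$chrom[i] == candidates$chrom[j] &&
        candidates$start[i] < candidates$end[j] &&
        candidates$end[i] > candidates$start[j]
      if (near_seq || same_locus) union_(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  fam_id <- vapply(unique(roots), function(r) {
    min(candidates$mature[roots == r])
  }, character(1))
  names(fam_id) <- as.character(unique(roots))
  dplyr::mutate(candidates, family = unname(fam_id[as.character(roots)]))
}

## substitution distance after aligning sequences at their 5' ends;
## length difference counts as mismatches
mature_distance <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  n <- min(la, lb)
  sum(seq_chars(substr(a, 1, n)) != seq_chars(substr(b, 1, n))) + abs(la - lb)
}

#' Label candidate families with known miRNAs
#'
#' A candidate matches a known mature miRNA when the two sequences differ
#' by at most `max_mismatch` substitutions with no gaps and their lengths
#' differ by at most `max_len_diff`. Every member of a family containing at
#' least one match inherits the known miRNA's name.
#'
#' @param candidates family-grouped candidate tibble (needs `mature`,
#'   `family`).
#' @param known named character vector of known mature sequences (empty
#'   means everything is novel).
#' @param max_mismatch substitution ceiling (default 2).
#' @param max_len_diff length-difference ceiling (default 2).
#' @return `candidates` with `known_match` (family-level name or `NA`),
#'   `direct_match` (this mature itself matched) and `novel`.
#' @export
match_known <- function(candidates, known = character(0), max_mismatch = 2,
                        max_len_diff = 2) {
  direct <- vapply(candidates$mature, function(m) {
    for (k in seq_along(known)) {
      if (abs(nchar(m) - nchar(known[k])) > max_len_diff) next
      n <- min(nchar(m), nchar(known[k]))
      mm <- sum(seq_chars(rna_to_dna(substr(m, 1, n))) !=
                  seq_chars(rna_to_dna(substr(known[k], 1, n))))
      if (mm <= max_mismatch) return(names(known)[k])
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  fam_label <- tapply(direct, candidates$family, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 0) x[1] else NA_character_
  })
  out <- dplyr::mutate(
    candidates,
    known_match = as.character(fam_label[.data$family]),
    direct_match = !is.na(direct))
  dplyr::mutate(out, novel = is.na(.data$known_match))
}

#' De novo miRNA discovery from processed tags
#'
#' Runs the full discovery chain: pooled-support seeding, window
#' enumeration per genome hit, fold-and-duplex evaluation (smallest
#' accepting extension wins), margin refold with annotation criteria,
#' family grouping and known-miRNA matching. Per-library CP10M expression
#' of each accepted mature tag is attached.
#'
#' @param processed output of [process_small_rna()] (`tags`, `hits`,
#'   `cp10m`, `mapped_total`).
#' @param genome named character vector.
#' @param known named character vector of known mature miRNAs.
#' @param min_reads pooled seed support (default 50).
#' @param max_ratio duplex mismatch-ratio ceiling (default 0.3).
#' @param margin refold margin in nt (default 15).
#' @param extensions window extension grid.
#' @param engine fold engine (see [fold()]); default `"vienna"`.
#' @param require_star_evidence require at least one mapped tag whose hit
#'   overlaps the predicted star interval by at least half the tag length
#'   (same strand). Detection of the star strand is standard supporting
#'   evidence for miRNA annotation and is what separates genuine
#'   duplex-producing loci from incidental hairpins around well-expressed
#'   tags (default `TRUE`).
#' @return tibble of accepted candidates: `mature`, `star`, `arm`, `chrom`,
#'   `start`, `end`, `strand` (refined precursor, 0-based half-open),
#'   `mismatch_ratio`, `family`, `known_match`, `novel`, plus one CP10M
#'   column per library. The rejection tally is in `attr(, "rejections")`.
#' @export
discover_mirnas <- function(processed, genome, known = character(0),
                            min_reads = 50, max_ratio = 0.3, margin = 15,
                            extensions = seq(100, 500, 100),
                            engine = "vienna",
                            require_star_evidence = TRUE) {
  seeds <- seed_candidates(processed$tags, min_reads)
  rejections <- character(0)
  rows <- list()
  for (i in seq_len(nrow(seeds))) {
    tag <- seeds$tag[i]
    hits <- processed$hits[processed$hits$tag == tag, , drop = FALSE]
    for (h in seq_len(nrow(hits))) {
      hit <- hits[h, ]
      wins <- enumerate_windows(hit, nchar(tag),
                                nchar(genome[[hit$chrom]]), extensions)
      ev <- evaluate_precursor(wins, nchar(tag), genome, max_ratio,
                               engine = engine)
      if (!ev$accepted) { rejections <- c(rejections, ev$reason); next }
      ref <- refine_with_margins(ev, genome, margin, engine = engine)
      if (!ref$accepted) { rejections <- c(rejections, ref$reason); next }
      if (require_star_evidence) {
        si <- ref$star_interval
        h <- processed$hits
        hend <- h$start + nchar(h$tag)
        overlap <- pmin(hend, si$end) - pmax(h$start, si$start)
        ok <- h$chrom == si$chrom & h$strand == si$strand &
          overlap >= nchar(h$tag) / 2
        if (!any(ok)) { rejections <- c(rejections, "no_star_reads"); next }
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(mature = tag, star = ref$star, arm = ref$arm),
        ref$precursor,
        tibble(mismatch_ratio = ref$duplex$mismatch_ratio,
               extension = ev$window$extension))
    }
  }
  if (length(rows) == 0) {
    out <- tibble(mature = character(), star = character(),
                  arm = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(),
                  mismatch_ratio = numeric(), extension = numeric(),
                  family = character(), known_match = character(),
                  novel = logical())
    attr(out, "rejections") <- table(rejections)
    return(out)
  }
  cand <- dplyr::bind_rows(rows)
  ## the same mature tag can enter through several hits; keep distinct loci
  cand <- dplyr::distinct(cand, .data$mature, .data$chrom, .data$start,
                          .data$end, .data$strand, .keep_all = TRUE)
  cand <- group_families(cand)
  cand <- match_known(cand, known)
  expr <- processed$cp10m
  cand <- dplyr::left_join(cand, expr, by = c(mature = "tag"))
  attr(cand, "rejections") <- table(rejections)
  cand
}
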