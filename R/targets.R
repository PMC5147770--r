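#' Score a miRNA:target alignment with the position-dependent penalty system
#'
#' Penalties per miRNA position: Watson-Crick pair 0, G:U wobble +0.5,
#' mismatch / single-nucleotide target bulge / single-nucleotide miRNA gap
#' +1. Each contribution is doubled when the lesion sits at miRNA positions
#' 2 to 13 counted from the miRNA 5' end (position 1 is single-weighted).
#' At most one position may be a bulge or a gap, never both.
#'
#' @param pairing character vector of per-miRNA-position states, 5'->3',
#'   from `c("WC", "GU", "mismatch", "target_bulge", "mirna_gap")`.
#' @return list with `score` (total penalty) and `penalties` (per-position
#'   contributions).
#' @examples
#' score_alignment(rep("WC", 21))$score            # 0
#' score_alignment(c(rep("WC", 4), "mismatch", rep("WC", 16)))$score  # 2
#' @export
score_alignment <- function(pairing) {
  states <- c("WC", "GU", "mismatch", "target_bulge", "mirna_gap")
  if (!all(pairing %in% states)) {
    stop("invalid pairing state: ",
         paste(setdiff(pairing, states), collapse = ", "))
  }
  if (sum(pairing %in% c("target_bulge", "mirna_gap")) > 1) {
    stop("at most one single-nucleotide bulge or gap is allowed")
  }
  base <- c(WC = 0, GU = 0.5, mismatch = 1, target_bulge = 1, mirna_gap = 1)
  pen <- unname(base[pairing])
  pos <- seq_along(pairing)
  pen[pos >= 2 & pos <= 13] <- 2 * pen[pos >= 2 & pos <= 13]
  list(score = sum(pen), penalties = pen)
}

## classify one miRNA base against one site base (both RNA, upper case).
## the miRNA pairs the site antiparallel.
pair_state <- function(mb, sb) {
  wc <- (mb == "A" && sb == "U") || (mb == "U" && sb == "A") ||
    (mb == "G" && sb == "C") || (mb == "C" && sb == "G")
  if (wc) return("WC")
  if ((mb == "G" && sb == "U") || (mb == "U" && sb == "G")) return("GU")
  "mismatch"
}

## pairing states for a gapless alignment of mirna (5'->3') against
## site (5'->3'); site position n-j+1 faces miRNA position j
gapless_states <- function(m, s) {
  n <- length(m)
  vapply(seq_len(n), function(p) pair_state(m[p], s[n - p + 1]),
         character(1))
}

#' Find the best-scoring alignment of a miRNA against one site window
#'
#' Enumerates every admissible alignment — the gapless alignment when the
#' window matches the miRNA length, all placements of exactly one
#' single-nucleotide target bulge when the window is one nt longer, all
#' placements of one single-nucleotide miRNA gap when one nt shorter — and
#' returns the minimum-score alignment. Ties go to the leftmost (smallest
#' miRNA position) bulge/gap placement.
#'
#' @param mirna mature miRNA, 5'->3'.
#' @param window candidate target subsequence, 5'->3', of length
#'   `nchar(mirna) + c(-1, 0, 1)`.
#' @return list `score`, `pairing` (per-miRNA-position states; the bulged
#'   target nucleotide is carried by the `target_bulge` state at the
#'   adjacent miRNA position), `lesion_pos` (miRNA position of the bulge or
#'   gap, `NA` if gapless).
#' @export
align_site <- function(mirna, window) {
  m <- seq_chars(dna_to_rna(mirna))
  s <- seq_chars(dna_to_rna(window))
  n <- length(m); w <- length(s)
  if (abs(w - n) > 1) {
    stop("window length must be within 1 nt of the miRNA length")
  }
  best <- NULL
  consider <- function(states, lesion_pos) {
    sc <- score_alignment(states)$score
    if (is.null(best) || sc < best$score ||
        (sc == best$score && !is.na(lesion_pos) && !is.na(best$lesion_pos) &&
         lesion_pos < best$lesion_pos)) {
      best <<- list(score = sc, pairing = states, lesion_pos = lesion_pos)
    }
  }
  if (w == n) {
    consider(gapless_states(m, s), NA_integer_)
  } else if (w == n + 1) {
    ## one extra target nucleotide: bulge adjacent to miRNA position b.
    ## site is read 3'->5' against the miRNA; skipping site index k means
    ## the bulge sits between miRNA positions facing k-1 and k+1.
    for (b in seq_len(n)) {
      ## miRNA position p faces site index (w - p + 1) for p < b and
      ## (w - p) for p > b; the skipped site nucleotide is at w - b + 1
      states <- character(n)
      for (p in seq_len(n)) {
        j <- if (p < b) w - p + 1 else w - p
        states[p] <- pair_state(m[p], s[j])
      }
      states[b] <- "target_bulge"
      consider(states, b)
    }
  } else {
    ## window one nt shorter: one miRNA position is unpaired (gap)
    for (b in seq_len(n)) {
      states <- character(n)
      for (p in seq_len(n)) {
        if (p == b) { states[p] <- "mirna_gap"; next }
        j <- if (p < b) w - p + 1 else w - p + 2
        states[p] <- pair_state(m[p], s[j])
      }
      consider(states, b)
    }
  }
  best
}

#' Scan transcripts for miRNA target sites
#'
#' Slides windows of length `nchar(mirna) - 1` to `nchar(mirna) + 1` over
#' each transcript, aligns each window with [align_site()], keeps the best
#' non-overlapping sites with penalty score at or below `max_score`, and
#' flags high-confidence sites (score at or below `hc_score`). On overlap
#' conflicts the lower-scoring site wins; ties go to the leftmost site.
#'
#' @param mirna mature miRNA sequence, 5'->3' (or a named character vector
#'   of several miRNAs).
#' @param transcripts named character vector of transcript sequences.
#' @param max_score retention threshold (default 6).
#' @param hc_score high-confidence threshold (default 5).
#' @return tibble `mirna`, `transcript`, `start` (0-based), `end`
#'   (half-open), `score`, `high_confidence`, `pairing` (compact string:
#'   `|` WC, `o` G:U, `.` mismatch, `-` bulge/gap), `cleavage`, ordered by
#'   (mirna, transcript, start).
#' @export
scan_transcriptome <- function(mirna, transcripts, max_score = 6,
                               hc_score = 5) {
  if (length(transcripts) == 0) {
    return(empty_predictions())
  }
  stopifnot(!is.null(names(transcripts)))
  mirnas <- if (is.null(names(mirna))) {
    setNames(mirna, paste0("mir", seq_along(mirna)))
  } else mirna
  out <- purrr::map_dfr(names(mirnas), function(mid) {
    mseq <- dna_to_rna(toupper(mirnas[[mid]]))
    purrr::map_dfr(names(transcripts), function(tid) {
      tseq <- dna_to_rna(toupper(transcripts[[tid]]))
      hits <- .scan_windows(mseq, tseq, max_score)
      if (nrow(hits) == 0) return(NULL)
      cand <- purrr::map_dfr(seq_len(nrow(hits)), function(k) {
        s0 <- hits$start[k]; w <- hits$width[k]
        al <- align_site(mseq, substr(tseq, s0 + 1, s0 + w))
        tibble(mirna = mid, transcript = tid, start = s0, end = s0 + w,
               score = al$score, pairing = pairing_string(al$pairing),
               cleavage = cleavage_from_alignment(s0, w, al$pairing))
      })
      keep_best_nonoverlapping(cand)
    })
  })
  if (nrow(out) == 0) return(empty_predictions())
  out$high_confidence <- out$score <= hc_score
  dplyr::arrange(out[, c("mirna", "transcript", "start", "end", "score",
                         "high_confidence", "pairing", "cleavage")],
                 .data$mirna, .data$transcript, .data$start)
}

empty_predictions <- function() {
  tibble(mirna = character(), transcript = character(), start = integer(),
         end = integer(), score = numeric(), high_confidence = logical(),
         pairing = character(), cleavage = integer())
}

pairing_string <- function(states) {
  paste(c(WC = "|", GU = "o", mismatch = ".", target_bulge = "-",
          mirna_gap = "-")[states], collapse = "")
}

## greedy selection of non-overlapping sites: lower score first, then
## leftmost
keep_best_nonoverlapping <- function(cand) {
  cand <- cand[order(cand$score, cand$start), , drop = FALSE]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    if (!any(row$start < kept$end & row$end > kept$start)) {
      kept <- dplyr::bind_rows(kept, row)
    }
  }
  kept[order(kept$start), , drop = FALSE]
}

## transcript coordinate of the canonical cleavage bond for an alignment
## placed at 0-based offset s0 with window width w. The returned integer b
## means cleavage between transcript positions b-1 and b (0-based): the
## bond between the target nucleotides paired to miRNA positions 10 and 11.
cleavage_from_alignment <- function(s0, w, states) {
  n <- length(states)
  if (n < 11) return(NA_integer_)
  ## site index (1-based within window) faced by miRNA position p
  site_index <- function(p) {
    lesion <- which(states %in% c("target_bulge", "mirna_gap"))
    if (length(lesion) == 0) return(w - p + 1)
    b <- lesion[1]
    if (states[b] == "target_bulge") {
      if (p < b) w - p + 1 else if (p > b) w - p else NA_integer_
    } else {
      if (p < b) w - p + 1 else if (p > b) w - p + 2 else NA_integer_
    }
  }
  flagged <- states[10] %in% c("target_bulge", "mirna_gap") ||
    states[11] %in% c("target_bulge", "mirna_gap")
  p10 <- 10; p11 <- 11
  if (flagged) {
    ## nearest paired flanking positions
    while (p10 >= 1 && states[p10] %in% c("target_bulge", "mirna_gap")) {
      p10 <- p10 - 1
    }
    while (p11 <= n && states[p11] %in% c("target_bulge", "mirna_gap")) {
      p11 <- p11 + 1
    }
    if (p10 < 1 || p11 > n) return(NA_integer_)
  }
  j11 <- site_index(p11)  # 5'-most of the two target nts (smaller index)
  b <- s0 + j11           # bond after site index j11 (0-based transcript)
  out <- as.integer(b)
  attr(out, "flagged") <- flagged
  out
}

#' Canonical cleavage position of a target prediction
#'
#' Returns the transcript coordinate of the bond between the target
#' nucleotides paired to miRNA positions 10 and 11 (counted from the miRNA
#' 5' end) — the canonical RISC slicing site. The returned integer `b`
#' denotes the bond between 0-based transcript positions `b - 1` and `b`.
#' If position 10 or 11 falls in a bulge/gap, the nearest paired flanking
#' bond is used and the result carries `attr(, "flagged") = TRUE`.
#'
#' @param prediction one row of the tibble from [scan_transcriptome()], or
#'   a list with `start`, `end`, `pairing`.
#' @return integer bond coordinate.
#' @export
predict_cleavage <- function(prediction) {
  states <- pairing_from_string(prediction$pairing[1])
  cleavage_from_alignment(prediction$start[1],
                          prediction$end[1] - prediction$start[1], states)
}

pairing_from_string <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  out <- c("|" = "WC", "o" = "GU", "." = "mismatch", "-" = "target_bulge")[ch]
  unname(out)
}

#' Fraction of RACE-observed cleavage ends at the canonical site
#'
#' @param observed_ends integer vector of cleavage bond coordinates mapped
#'   from 5'-RACE clones.
#' @param canonical_site the canonical bond coordinate (between the target
#'   nucleotides paired to miRNA positions 10 and 11).
#' @return fraction of ends equal to the canonical site.
#' @examples
#' race_fraction(c(rep(111, 5), rep(108, 10)), 111)  # 1/3
#' @export
race_fraction <- function(observed_ends, canonical_site) {
  if (length(observed_ends) == 0) stop("no observed cleavage ends")
  mean(observed_ends == canonical_site)
}
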