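#' Fold a sequence by base-pair maximization
#'
#' Computes a maximum base-pair nested secondary structure (Nussinov-style
#' dynamic programming) with a minimum hairpin loop. This deliberately
#' replaces thermodynamic minimum-free-energy folding: the discovery
#' pipeline only needs hairpin/duplex topology and a mismatch ratio, both of
#' which survive the simplification, and the interface (sequence in,
#' pair table out) is a seam where a thermodynamic folder can be substituted.
#'
#' Admissible pairs are A:U, G:C and the G:U wobble; T is treated as U.
#' The traceback is deterministic: scanning 5' to 3', each position pairs the
#' smallest admissible partner consistent with an optimal structure.
#'
#' The `"vienna"` engine instead shells out to `RNAfold` (ViennaRNA) for a
#' thermodynamic minimum-free-energy structure through the same interface;
#' the discovery pipeline uses it by default because on windows hundreds of
#' nt long, maximum-pairing structures saturate random background with
#' incidental pairs and no longer isolate the miRNA/miRNA* duplex, whereas
#' the MFE structure does. `min_loop` only applies to the `"nussinov"`
#' engine.
#'
#' @param sequence a single DNA/RNA string.
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @param engine `"nussinov"` (base-pair maximization, self-contained) or
#'   `"vienna"` (`RNAfold` MFE).
#' @return an object of class `fold_result`: list with `sequence` (as given,
#'   upper case), `pair_table` (integer vector, 1-based partner index or `NA`
#'   if unpaired), `n_pairs`, and `dot_bracket`.
#' @examples
#' fold("GGGAAACCC")$n_pairs
#' @export
fold <- function(sequence, min_loop = 3, engine = c("nussinov", "vienna")) {
  engine <- match.arg(engine)
  stopifnot(length(sequence) == 1, is.character(sequence))
  seq_up <- dna_to_rna(toupper(sequence))
  if (grepl("[^ACGUN]", seq_up)) {
    stop("invalid alphabet in sequence: expected A/C/G/T/U/N")
  }
  n <- nchar(seq_up)
  if (n < min_loop + 2) {
    stop("sequence shorter than min_loop + 2 (", min_loop + 2, " nt)")
  }
  partner <- if (engine == "vienna") {
    dotbracket_to_pair_table(rnafold_dotbracket(seq_up))
  } else {
    .nussinov_fold(seq_up, as.integer(min_loop))
  }
  structure(
    list(
      sequence = toupper(sequence),
      pair_table = partner,
      n_pairs = sum(!is.na(partner)) / 2L,
      dot_bracket = pair_table_to_dotbracket(partner)
    ),
    class = "fold_result"
  )
}

## MFE dot-bracket from the RNAfold binary (one sequence)
rnafold_dotbracket <- function(seq_rna) {
  if (Sys.which("RNAfold") == "") {
    stop("the 'vienna' fold engine needs the RNAfold binary on PATH")
  }
  out <- system2("RNAfold", "--noPS", input = seq_rna, stdout = TRUE)
  sub("\\s.*$", "", out[2])
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result> ", nchar(x$sequence), " nt, ", x$n_pairs, " pairs\n",
      sep = "")
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Convert a pair table to dot-bracket notation
#'
#' @param pair_table 1-based partner vector with `NA` for unpaired positions.
#' @return a dot-bracket string.
#' @export
pair_table_to_dotbracket <- function(pair_table) {
  n <- length(pair_table)
  db <- rep(".", n)
  paired <- which(!is.na(pair_table))
  db[paired[pair_table[paired] > paired]] <- "("
  db[paired[pair_table[paired] < paired]] <- ")"
  paste(db, collapse = "")
}

#' Convert dot-bracket notation to a pair table
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return integer partner vector (1-based, `NA` unpaired).
#' @export
dotbracket_to_pair_table <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  pt
}

#' Extract the miRNA/miRNA* duplex from a folded precursor
#'
#' Given a fold of a precursor and the mature miRNA interval within it,
#' locates the star arm as the minimal interval containing all partners of
#' mature positions, extended 2 nt at its 3' end (the canonical 2-nt 3'
#' overhang of plant miRNA duplexes), and computes the duplex mismatch
#' ratio: the fraction of mature positions with no partner, mature length
#' in the denominator.
#'
#' @param fold a `fold_result`.
#' @param mature_start 1-based start of the mature sequence in the precursor.
#' @param mature_length mature length in nt.
#' @param star_offset 3'-overhang extension of the star interval (default 2).
#' @return a tibble with one row: `mature_start`, `mature_end`, `star_start`,
#'   `star_end` (1-based inclusive; star columns `NA` when nothing pairs),
#'   `paired` (mature positions with a partner), `mismatch_ratio`,
#'   `star_span` (raw partner span before the 3' extension) and
#'   `mature_paired_span` (span from first to last paired mature position;
#'   comparing it against `star_span` measures the asymmetric bulge within
#'   the duplex).
#' @export
extract_duplex <- function(fold, mature_start, mature_length,
                           star_offset = 2) {
  n <- length(fold$pair_table)
  mature_end <- mature_start + mature_length - 1
  stopifnot(mature_start >= 1, mature_end <= n)
  idx <- mature_start:mature_end
  partners <- fold$pair_table[idx]
  paired <- sum(!is.na(partners))
  if (paired == 0) {
    return(tibble(
      mature_start = mature_start, mature_end = mature_end,
      star_start = NA_integer_, star_end = NA_integer_,
      paired = 0L, mismatch_ratio = 1, star_span = 0L,
      mature_paired_span = 0L
    ))
  }
  p <- partners[!is.na(partners)]
  star_start <- min(p)
  star_end <- min(max(p) + star_offset, n)
  tibble(
    mature_start = mature_start, mature_end = mature_end,
    star_start = as.integer(star_start), star_end = as.integer(star_end),
    paired = as.integer(paired),
    mismatch_ratio = (mature_length - paired) / mature_length,
    star_span = as.integer(max(p) - min(p) + 1L),
    mature_paired_span = as.integer(diff(range(idx[!is.na(partners)])) + 1L)
  )
}

## nesting-forest of pairs: returns a list with per-pair parent and the
## number of pairs in each subtree ("branch weight")
pair_forest <- function(pair_table) {
  opens <- which(!is.na(pair_table) & pair_table > seq_along(pair_table))
  if (length(opens) == 0) {
    return(list(open = integer(0), close = integer(0), parent = integer(0),
                weight = integer(0)))
  }
  close <- pair_table[opens]
  ord <- order(opens)
  opens <- opens[ord]; close <- close[ord]
  parent <- integer(length(opens))
  stack <- integer(0)
  for (k in seq_along(opens)) {
    while (length(stack) > 0 && close[stack[length(stack)]] < opens[k]) {
      stack <- stack[-length(stack)]
    }
    parent[k] <- if (length(stack) > 0) stack[length(stack)] else 0L
    stack <- c(stack, k)
  }
  weight <- rep(1L, length(opens))
  for (k in rev(seq_along(opens))) {
    if (parent[k] > 0) weight[parent[k]] <- weight[parent[k]] + weight[k]
  }
  list(open = opens, close = close, parent = parent, weight = weight)
}

#' Does a fold form a single hairpin?
#'
#' `TRUE` iff the paired regions form one stem: after discarding branches
#' whose subtree contains fewer than `min_branch_pairs` pairs (incidental
#' pairing that any maximum-pairing fold accumulates in flanking sequence),
#' no position of the structure encloses two disjoint helices and only one
#' helix chain exists at the top level. A structure with zero retained pairs
#' is not a hairpin.
#'
#' @param fold a `fold_result`.
#' @param min_branch_pairs branches smaller than this are ignored when
#'   counting stems (default 8; larger than any helix a short random flank
#'   can form, smaller than a genuine miRNA duplex arm).
#' @return logical scalar.
#' @export
is_single_hairpin <- function(fold, min_branch_pairs = 8) {
  f <- pair_forest(fold$pair_table)
  if (length(f$open) == 0) return(FALSE)
  keep <- f$weight >= min_branch_pairs
  if (!any(keep)) return(FALSE)
  ## effective parent: nearest retained ancestor
  eff_parent <- function(k) {
    p <- f$parent[k]
    while (p > 0 && !keep[p]) p <- f$parent[p]
    p
  }
  parents <- vapply(which(keep), eff_parent, integer(1))
  ## single stem <=> every retained node has at most one retained child and
  ## exactly one retained root
  if (sum(parents == 0L) != 1L) return(FALSE)
  !any(duplicated(parents[parents > 0L]))
}
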