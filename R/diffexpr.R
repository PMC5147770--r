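#' FPKM / RPKM from a count matrix
#'
#' `count * 1e9 / (length_nt * total)` — fragments (or reads) per kilobase
#' of transcript per million mapped.
#'
#' @param counts tibble with `feature` and one count column per library.
#' @param lengths named numeric vector of feature lengths in nt.
#' @param totals named numeric vector of per-library mapped totals; defaults
#'   to the column sums of `counts`.
#' @return tibble of the same shape with FPKM values.
#' @export
compute_fpkm <- function(counts, lengths, totals = NULL) {
  libs <- setdiff(names(counts), "feature")
  len <- lengths[counts$feature]
  if (any(is.na(len)) || any(len <= 0)) {
    stop("missing or non-positive length for some features")
  }
  totals <- totals %||% vapply(counts[libs], sum, numeric(1))
  if (any(totals <= 0)) stop("non-positive library total")
  out <- counts
  for (l in libs) {
    out[[l]] <- unname(counts[[l]] * 1e9 / (len * totals[[l]]))
  }
  out
}

#' Replicate reproducibility as log-FPKM Pearson correlation
#'
#' For each replicate pair, keeps genes with FPKM above `min_fpkm`
#' (strictly) in both replicates and reports the Pearson correlation of
#' `log2(FPKM + 1)`.
#'
#' @param fpkm FPKM tibble from [compute_fpkm()].
#' @param pairs tibble with `sample`, `rep1`, `rep2` (library column names);
#'   if missing, columns are paired by stripping a trailing `_1` / `_2`.
#' @param min_fpkm expression floor, strict inequality (default 0.5).
#' @return tibble `sample`, `n_genes`, `r` (`NA` with a warning if fewer
#'   than 3 genes pass).
#' @export
replicate_correlation <- function(fpkm, pairs = NULL, min_fpkm = 0.5) {
  libs <- setdiff(names(fpkm), "feature")
  if (is.null(pairs)) {
    base <- sub("_[0-9]+$", "", libs)
    pairs <- purrr::map_dfr(unique(base[duplicated(base)]), function(b) {
      reps <- libs[base == b]
      tibble(sample = b, rep1 = reps[1], rep2 = reps[2])
    })
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    x <- fpkm[[pairs$rep1[i]]]; y <- fpkm[[pairs$rep2[i]]]
    keep <- x > min_fpkm & y > min_fpkm
    if (sum(keep) < 3) {
      warning("fewer than 3 genes pass the FPKM filter for ",
              pairs$sample[i], "; correlation undefined")
      return(tibble(sample = pairs$sample[i], n_genes = sum(keep),
                    r = NA_real_))
    }
    tibble(sample = pairs$sample[i], n_genes = sum(keep),
           r = cor(log2(x[keep] + 1), log2(y[keep] + 1)))
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin, input-checked surface
#' over the standard implementation so the pipeline has a single named
#' entry point for multiple-testing correction.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

## two-sided conditional exact p for pooled counts k1, k2 out of library
## totals t1, t2 (2x2: feature vs rest, condition 1 vs 2)
exact_count_test <- function(k1, t1, k2, t2) {
  m <- matrix(c(k1, t1 - k1, k2, t2 - k2), nrow = 2)
  stats::fisher.test(m)$p.value
}

#' Differential miRNA expression between two conditions
#'
#' Counts are pooled across the replicate libraries of each condition; the
#' per-feature p-value is a two-sided conditional exact test of the pooled
#' count against the pooled library total (2x2 hypergeometric), adjusted by
#' Benjamini-Hochberg across all tested features. The fold change is the
#' ratio of mean CP10M with a 0.5 pseudo-count added to raw counts before
#' normalization. A feature is called `up`/`down` only when both the fold
#' change and the adjusted p-value pass their thresholds.
#'
#' @param counts tibble `feature` plus one raw count column per library.
#' @param contrast list with `cond1` and `cond2`, each a character vector
#'   of library column names; direction `up` means higher in `cond1`.
#' @param min_fc minimum fold change, either direction (default 1.5,
#'   inclusive).
#' @param alpha BH-adjusted significance level (default 0.05, strict).
#' @param totals optional named vector of per-library mapped totals;
#'   defaults to column sums of `counts`.
#' @return an `ethy_diff` tibble: `feature`, `mean_1`, `mean_2` (CP10M),
#'   `fold_change`, `log2fc`, `p`, `padj`, `direction`.
#' @export
diff_mirna <- function(counts, contrast, min_fc = 1.5, alpha = 0.05,
                       totals = NULL) {
  libs <- c(contrast$cond1, contrast$cond2)
  stopifnot(all(libs %in% names(counts)))
  totals <- totals %||% vapply(counts[libs], sum, numeric(1))
  if (any(totals[libs] == 0)) stop("a condition has zero library total")
  t1 <- sum(totals[contrast$cond1]); t2 <- sum(totals[contrast$cond2])
  k1 <- rowSums(counts[, contrast$cond1, drop = FALSE])
  k2 <- rowSums(counts[, contrast$cond2, drop = FALSE])
  pseudo <- 0.5
  cp1 <- (k1 + pseudo) * 1e7 / t1
  cp2 <- (k2 + pseudo) * 1e7 / t2
  p <- vapply(seq_along(k1), function(i) exact_count_test(k1[i], t1, k2[i], t2),
              numeric(1))
  padj <- bh_adjust(p)
  fc <- cp1 / cp2
  ratio <- pmax(fc, 1 / fc)
  direction <- dplyr::case_when(
    ratio >= min_fc & padj < alpha & fc > 1 ~ "up",
    ratio >= min_fc & padj < alpha & fc < 1 ~ "down",
    .default = "ns")
  out <- tibble(feature = counts$feature, mean_1 = cp1, mean_2 = cp2,
                fold_change = fc, log2fc = log2(fc), p = p, padj = padj,
                direction = direction)
  new_ethy_diff(out, contrast = contrast, min_fc = min_fc, alpha = alpha,
                unit = "CP10M")
}

#' Differential gene expression between two conditions
#'
#' Same machinery as [diff_mirna()] on gene counts, with FPKM/RPKM means
#' and an expression floor applied before testing: only genes reaching
#' `min_expr` RPKM in at least one condition are tested. The default fold
#' change is 2; the alternative 1.5 convention is available through
#' `min_fc`.
#'
#' @inheritParams diff_mirna
#' @param lengths named numeric vector of gene lengths (nt).
#' @param min_fc minimum fold change (default 2, inclusive).
#' @param min_expr RPKM floor: genes below it in both conditions are not
#'   tested (default 1, strict "larger than").
#' @return an `ethy_diff` tibble (filtered genes absent), means in FPKM.
#' @export
diff_gene <- function(counts, lengths, contrast, min_fc = 2, alpha = 0.05,
                      min_expr = 1, totals = NULL) {
  libs <- c(contrast$cond1, contrast$cond2)
  stopifnot(all(libs %in% names(counts)))
  totals <- totals %||% vapply(counts[libs], sum, numeric(1))
  if (any(totals[libs] == 0)) stop("a condition has zero library total")
  len <- lengths[counts$feature]
  t1 <- sum(totals[contrast$cond1]); t2 <- sum(totals[contrast$cond2])
  k1 <- rowSums(counts[, contrast$cond1, drop = FALSE])
  k2 <- rowSums(counts[, contrast$cond2, drop = FALSE])
  pseudo <- 0.5
  fpkm1 <- (k1 + pseudo) * 1e9 / (len * t1)
  fpkm2 <- (k2 + pseudo) * 1e9 / (len * t2)
  tested <- fpkm1 > min_expr | fpkm2 > min_expr
  idx <- which(tested)
  p <- vapply(idx, function(i) exact_count_test(k1[i], t1, k2[i], t2),
              numeric(1))
  padj <- bh_adjust(p)
  fc <- fpkm1[idx] / fpkm2[idx]
  ratio <- pmax(fc, 1 / fc)
  direction <- dplyr::case_when(
    ratio >= min_fc & padj < alpha & fc > 1 ~ "up",
    ratio >= min_fc & padj < alpha & fc < 1 ~ "down",
    .default = "ns")
  out <- tibble(feature = counts$feature[idx], mean_1 = fpkm1[idx],
                mean_2 = fpkm2[idx], fold_change = fc, log2fc = log2(fc),
                p = p, padj = padj, direction = direction)
  new_ethy_diff(out, contrast = contrast, min_fc = min_fc, alpha = alpha,
                unit = "FPKM", n_filtered = sum(!tested))
}

new_ethy_diff <- function(x, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c("ethy_diff", class(x))
  x
}

#' @export
print.ethy_diff <- function(x, ...) {
  n_up <- sum(x$direction == "up"); n_dn <- sum(x$direction == "down")
  cat("<ethy_diff> ", nrow(x), " features tested (", attr(x, "unit"),
      "), min fold change ", attr(x, "min_fc"), ", alpha ",
      attr(x, "alpha"), "\n", "  up: ", n_up, "  down: ", n_dn,
      "  ns: ", sum(x$direction == "ns"), "\n", sep = "")
  NextMethod()
}
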