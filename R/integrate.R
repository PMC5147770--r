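#' Venn partition of two feature sets
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return list with `counts` (named: `a_only`, `shared`, `b_only`) and
#'   `members` (list of the three member vectors).
#' @export
venn_counts <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  members <- list(a_only = setdiff(a, b), shared = intersect(a, b),
                  b_only = setdiff(b, a))
  list(counts = vapply(members, length, integer(1)), members = members)
}

#' Features differential in root but not in shoot
#'
#' @param root_set,shoot_set character vectors of differential feature ids
#'   from the same genotype and contrast.
#' @return root-only member vector.
#' @export
tissue_specific <- function(root_set, shoot_set) {
  setdiff(unique(root_set), unique(shoot_set))
}

#' CBP20-dependent differential features
#'
#' Features called differential (direction not `ns`) in the wild type but
#' `ns` in the mutant under the same contrast and thresholds. When the two
#' call tables cover different feature universes, the comparison is
#' restricted to the intersection with a warning.
#'
#' @param wt_calls,mutant_calls `ethy_diff` tibbles (or any tibble with
#'   `feature` and `direction`).
#' @return list with `dependent` (feature ids), `fraction` (per-direction
#'   tibble: `direction`, `n_wt`, `n_dependent`, `fraction`), and
#'   `universe` (features compared).
#' @export
cbp20_dependent <- function(wt_calls, mutant_calls) {
  universe <- intersect(wt_calls$feature, mutant_calls$feature)
  if (length(universe) < length(unique(wt_calls$feature)) ||
      length(universe) < length(unique(mutant_calls$feature))) {
    warning("feature universes differ; restricting to their intersection (",
            length(universe), " features)")
  }
  wt <- wt_calls[wt_calls$feature %in% universe, ]
  mt <- mutant_calls[mutant_calls$feature %in% universe, ]
  mt_dir <- setNames(mt$direction, mt$feature)
  wt_diff <- wt[wt$direction != "ns", ]
  dep <- wt_diff$feature[mt_dir[wt_diff$feature] == "ns"]
  fraction <- wt_diff %>%
    dplyr::group_by(direction = .data$direction) %>%
    dplyr::summarise(n_wt = dplyr::n(),
                     n_dependent = sum(.data$feature %in% dep),
                     .groups = "drop") %>%
    dplyr::mutate(fraction = .data$n_dependent / .data$n_wt)
  list(dependent = dep, fraction = fraction, universe = universe)
}

#' Pair differential miRNAs with anti-correlated predicted targets
#'
#' Returns (miRNA, target) pairs where the target is predicted for the
#' miRNA, both are differential in the same contrast with opposite
#' directions, with the CBP20-dependence flag taken from the supplied
#' dependence sets.
#'
#' @param mirna_calls,gene_calls `ethy_diff` tibbles for the same contrast.
#' @param predictions prediction tibble from [scan_transcriptome()].
#' @param dependence optional list with `mirna` and `gene` character
#'   vectors of CBP20-dependent feature ids (from [cbp20_dependent()]).
#' @return tibble `mirna`, `target`, `mirna_direction`, `target_direction`,
#'   `t_score`, `cleavage`, `cbp20_dependent`, sorted by (mirna, t_score).
#' @export
anticorrelated_pairs <- function(mirna_calls, gene_calls, predictions,
                                 dependence = NULL) {
  m_diff <- mirna_calls[mirna_calls$direction != "ns",
                        c("feature", "direction")]
  g_diff <- gene_calls[gene_calls$direction != "ns",
                       c("feature", "direction")]
  if (nrow(predictions) == 0 || nrow(m_diff) == 0 || nrow(g_diff) == 0) {
    return(tibble(mirna = character(), target = character(),
                  mirna_direction = character(),
                  target_direction = character(), t_score = numeric(),
                  cleavage = integer(), cbp20_dependent = logical()))
  }
  out <- predictions %>%
    dplyr::inner_join(dplyr::rename(m_diff, mirna = "feature",
                                    mirna_direction = "direction"),
                      by = "mirna") %>%
    dplyr::inner_join(dplyr::rename(g_diff, transcript = "feature",
                                    target_direction = "direction"),
                      by = "transcript") %>%
    dplyr::filter(.data$mirna_direction != .data$target_direction) %>%
    dplyr::transmute(
      mirna = .data$mirna, target = .data$transcript,
      mirna_direction = .data$mirna_direction,
      target_direction = .data$target_direction,
      t_score = .data$score, cleavage = .data$cleavage,
      cbp20_dependent = if (is.null(dependence)) NA else
        .data$mirna %in% dependence$mirna &
        .data$transcript %in% dependence$gene)
  dplyr::arrange(out, .data$mirna, .data$t_score)
}

#' Expression matrix of differential features for heat-map display
#'
#' Rows are the requested features ordered by direction (up first) then
#' descending absolute fold change; values are log2(normalized
#' expression + 1).
#'
#' @param calls `ethy_diff` tibble (for ordering).
#' @param expression tibble `feature`/`tag` plus per-library normalized
#'   values.
#' @param features features to include (default: all differential).
#' @return tibble `feature`, `direction`, then one column per library.
#' @export
export_heatmap_matrix <- function(calls, expression, features = NULL) {
  key <- intersect(c("feature", "tag"), names(expression))[1]
  features <- features %||% calls$feature[calls$direction != "ns"]
  sel <- calls[calls$feature %in% features, ]
  sel <- sel[order(factor(sel$direction, levels = c("up", "down", "ns")),
                   -abs(sel$log2fc)), ]
  expr <- expression[match(sel$feature, expression[[key]]), ]
  libs <- setdiff(names(expression), key)
  out <- dplyr::bind_cols(tibble(feature = sel$feature,
                                 direction = sel$direction),
                          purrr::map_dfc(expr[libs], ~log2(.x + 1)))
  out
}
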