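#' Length by 5'-nucleotide profile plot
#'
#' Bar chart of CP10M by tag length, filled by 5'-nucleotide, faceted by
#' library — the standard small-RNA composition diagnostic.
#'
#' @param profile tibble from [length_5p_profile()].
#' @return a ggplot object.
#' @export
plot_length_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$length), y = .data$cp10m,
                               fill = .data$first_nt)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~library) +
    ggplot2::labs(x = "tag length (nt)", y = "CP10M",
                  fill = "5' nucleotide") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a differential-expression result
#'
#' @param object an `ethy_diff` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ethy_diff <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat-map of differential features
#'
#' Tile plot of the matrix from [export_heatmap_matrix()].
#'
#' @param heat tibble from [export_heatmap_matrix()].
#' @return a ggplot object.
#' @export
plot_expression_heatmap <- function(heat) {
  long <- tidyr::pivot_longer(heat, -c("feature", "direction"),
                              names_to = "library", values_to = "log2expr")
  long$feature <- factor(long$feature, levels = rev(unique(heat$feature)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$library, y = .data$feature,
                                     fill = .data$log2expr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2(expr + 1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
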