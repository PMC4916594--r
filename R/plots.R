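# ggplot2 visualisations of the main result types.

#' Plot sample PCA coordinates
#'
#' @param object A `sample_pca` object.
#' @param ... Unused.
#' @return A ggplot: PC1 vs PC2, coloured by tissue when available.
#' @export
autoplot.sample_pca <- function(object, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if ("tissue" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$tissue), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Plot module sizes
#'
#' @param object A `coexpression_modules` object.
#' @param ... Unused.
#' @return A ggplot bar chart of module sizes (gray bar = unassigned).
#' @export
autoplot.coexpression_modules <- function(object, ...) {
  sizes <- dplyr::count(object$assignments, .data$module)
  sizes$label <- ifelse(sizes$module == 0L, "gray", as.character(sizes$module))
  sizes$label <- factor(sizes$label, levels = sizes$label[order(-sizes$n)])
  ggplot2::ggplot(sizes, ggplot2::aes(.data$label, .data$n,
                                      fill = .data$module == 0L)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "gray60", `FALSE` = "steelblue")) +
    ggplot2::labs(x = "module", y = "transcripts") +
    ggplot2::theme_minimal()
}

#' Tissue-specificity heatmap
#'
#' Tile heatmap of the per-transcript Z-scored tissue profiles produced by
#' [zscore_matrix()], with rows in tissue-block order.
#'
#' @param zscores Tibble from [zscore_matrix()].
#' @return A ggplot.
#' @export
plot_specificity_heatmap <- function(zscores) {
  meta <- c("transcript_id", "specific_tissue", "class")
  long <- tidyr::pivot_longer(zscores, -dplyr::all_of(intersect(meta, names(zscores))),
                              names_to = "tissue", values_to = "z")
  long$transcript_id <- factor(long$transcript_id,
                               levels = rev(zscores$transcript_id))
  ggplot2::ggplot(long, ggplot2::aes(.data$tissue, .data$transcript_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-tissue counts of specific transcripts
#'
#' @param counts Tibble from [count_specific()].
#' @return A ggplot bar chart, tissues ordered by total count.
#' @export
plot_specific_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts[c("tissue", "TSCT", "TSNT")],
                              c("TSCT", "TSNT"),
                              names_to = "class", values_to = "n")
  long$tissue <- factor(long$tissue, levels = counts$tissue)
  ggplot2::ggplot(long, ggplot2::aes(.data$tissue, .data$n, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "specific transcripts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
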