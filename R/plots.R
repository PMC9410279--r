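#' Heatmap of a hit table
#'
#' Subject-by-reference tiles shaded by bit score (darker = stronger hit);
#' absent pairs are blank. The plot is the figure-style view of
#' [hit_matrix()].
#'
#' @param object An `lu_hit_table`.
#' @param fill `"bit_score"` or `"evalue"` (E-values are shown on a -log10
#'   scale).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lu_hit_table
#' @export
autoplot.lu_hit_table <- function(object, fill = c("bit_score", "evalue"),
                                  ...) {
  fill <- match.arg(fill)
  df <- tibble::as_tibble(object)
  if (fill == "evalue") {
    df$value <- -log10(df$evalue)
    legend <- "-log10(E)"
  } else {
    df$value <- df$bit_score
    legend <- "bit score"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$query_id, y = .data$subject_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient(low = "grey95", high = "grey10",
                                 na.value = "white", name = legend) +
    ggplot2::labs(x = "reference LU-domain", y = "proteome subject") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a grouped-similarity matrix
#'
#' @param object An `lu_similarity` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lu_similarity
#' @export
autoplot.lu_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id_a, y = .data$id_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 limits = c(0, 100), name = "% similarity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a guide tree
#'
#' Midpoint-rooted rendering of the neighbor-joining guide tree via
#' [ape::plot.phylo()].
#'
#' @param tree A `phylo` tree from [neighbor_joining()].
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly.
#' @export
plot_guide_tree <- function(tree, ...) {
  ape::plot.phylo(rooted_for_display(tree), ...)
  invisible(tree)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
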