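#' QC and result plots
#'
#' ggplot2 views of the main result objects: PCA of samples, the sample
#' correlation heatmap, per-comparison up/down DE counts, and the ceRNA
#' network (via [autoplot][ggplot2::autoplot]).
#'
#' @param pca a [pca_coordinates()] result.
#' @param samples optional sample sheet used to colour points by stage.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
plot_pca <- function(pca, samples = NULL) {
  stopifnot(inherits(pca, "sample_pca"))
  d <- pca$scores
  if (!is.null(samples)) d <- left_join(d, samples, by = "sample_id")
  ve <- pca$variance_explained
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(samples)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
}

#' @rdname plots
#' @param corr a correlation matrix from [sample_correlation()].
#' @export
plot_sample_correlation <- function(corr) {
  d <- as_tibble(corr, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "r")
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_a, .data$sample_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick", limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname plots
#' @param de a tidy DE table from [call_de()].
#' @export
plot_de_counts <- function(de) {
  d <- de |>
    filter(.data$status != "ns") |>
    dplyr::count(.data$comparison, .data$status)
  ggplot2::ggplot(d, ggplot2::aes(.data$comparison, .data$n, fill = .data$status)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "firebrick", down = "steelblue")) +
    ggplot2::labs(x = NULL, y = "DE features", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plots
#' @param object a `cerna_network`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cerna_network <- function(object, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::theme_void() +
      ggplot2::labs(title = "empty ceRNA network"))
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(object$edges),
    vertices = as.data.frame(object$nodes), directed = FALSE
  )
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |> mutate(x = xy[, 1], y = xy[, 2])
  lookup <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  edges <- object$edges |>
    mutate(
      x = nodes$x[lookup[.data$from]], y = nodes$y[lookup[.data$from]],
      xend = nodes$x[lookup[.data$to]], yend = nodes$y[lookup[.data$to]]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        linetype = .data$edge_type
      ),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y,
        colour = .data$type, size = .data$connectivity
      )
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, size = "connectivity", linetype = NULL)
}
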