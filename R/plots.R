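#' Plot a permutation null with an observed count
#'
#' Histogram of the permutation null distribution of damaged-gene counts with
#' the observed count marked, the standard way to display a gene-list
#' enrichment result.
#'
#' @param object A `perm_null` from [build_null()].
#' @param observed Optional observed damaged-gene count to mark.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.perm_null <- function(object, observed = NULL, ...) {
  df <- tibble::tibble(count = object$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue", colour = NA) +
    ggplot2::labs(
      x = sprintf("damaged genes in random lists of %d (P = %d)", object$N, object$P),
      y = "draws",
      title = sprintf("Permutation null (%s mode)", object$mode)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red",
                                 linetype = 2)
  }
  p
}

#' Plot enrichment Z-scores by gene list and mode
#'
#' Dot plot of the Z-standardized enrichment of each gene list per inheritance
#' mode, the cross-list comparison the Z transform enables.
#'
#' @param enrichment Tibble from [test_enrichment()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$z, y = .data$list, colour = .data$mode)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Z-score (observed vs permutation null)", y = NULL,
                  colour = "mode") +
    ggplot2::theme_minimal()
}

#' Plot a moralized belief network
#'
#' Draws the undirected moral graph on a circular layout; edge width encodes
#' dependency strength, colour the sign (blue positive, red negative, grey
#' multistate).
#'
#' @param edges Tibble from [moralize()] (a fitted model gives annotated
#'   edges).
#' @return A ggplot object.
#' @export
plot_moral_graph <- function(edges) {
  nodes <- sort(unique(c(edges$node1, edges$node2)))
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  layout <- tibble::tibble(node = nodes, x = cos(theta), y = sin(theta))
  seg <- edges |>
    dplyr::left_join(layout, by = c(node1 = "node")) |>
    dplyr::rename(x1 = "x", y1 = "y") |>
    dplyr::left_join(layout, by = c(node2 = "node")) |>
    dplyr::rename(x2 = "x", y2 = "y")
  if (!"strength" %in% names(seg)) seg$strength <- 1
  if (!"sign" %in% names(seg)) seg$sign <- NA_real_
  seg$assoc <- factor(dplyr::case_when(is.na(seg$sign) ~ "multistate",
                                       seg$sign > 0 ~ "positive",
                                       TRUE ~ "negative"),
                      levels = c("positive", "negative", "multistate"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2,
                   linewidth = .data$strength, colour = .data$assoc)) +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y, label = .data$node)) +
    ggplot2::scale_colour_manual(values = c(positive = "steelblue",
                                            negative = "firebrick",
                                            multistate = "grey60")) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "association", linewidth = "strength")
}
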