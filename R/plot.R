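# ggplot2 views of a fit: the clustering itself, the density field, and the
# cluster-number frequency profile used to pick the stable count.

#' Plot a densitycut fit
#'
#' @param object A `densitycut` object fitted on point data.
#' @param type `"clusters"` (scatter coloured by selected cluster),
#'   `"density"` (scatter coloured by refined density) or `"frequency"`
#'   (cluster-count persistence over the saliency sweep).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.densitycut <- function(object, type = c("clusters", "density",
                                                 "frequency"), ...) {
  type <- match.arg(type)
  if (type == "frequency") return(plot_cluster_frequency(object))
  if (is.null(object$data)) {
    dc_abort_parameter("fit has no coordinates (graph-only input); only type = \"frequency\" can be plotted")
  }
  df <- as_tibble(object$data[, 1:2, drop = FALSE], .name_repair = "minimal")
  names(df) <- c(".x", ".y")
  if (type == "clusters") {
    df$cluster <- factor(object$labels)
    ggplot2::ggplot(df, ggplot2::aes(.data$.x, .data$.y,
                                     colour = .data$cluster)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "dim 1", y = "dim 2", colour = "cluster") +
      ggplot2::theme_minimal()
  } else {
    df$f <- object$f$values
    ggplot2::ggplot(df, ggplot2::aes(.data$.x, .data$.y, colour = .data$f)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_colour_viridis_c() +
      ggplot2::labs(x = "dim 1", y = "dim 2", colour = "density") +
      ggplot2::theme_minimal()
  }
}

#' Cluster-number frequency plot
#'
#' How many saliency-threshold levels each cluster count persisted for; the
#' tallest bar is the selected clustering.
#'
#' @param x A `densitycut` or `dc_merge_tree` object.
#' @return A ggplot object.
#' @export
plot_cluster_frequency <- function(x) {
  tree <- if (inherits(x, "densitycut")) x$tree else x
  stopifnot(inherits(tree, "dc_merge_tree"))
  df <- tree$frequency
  df$selected <- df$count == tree$selected_count
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$count), .data$frequency,
                                   fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "number of clusters",
                  y = "frequency (threshold levels)") +
    ggplot2::theme_minimal()
}
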