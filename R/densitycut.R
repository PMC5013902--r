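# The end-to-end pipeline: Knn graph -> Knn density -> random-walk
# refinement -> mode forest -> saliency sweep -> stable clustering.

dc_run_stages <- function(graph, f0, alpha, tol, max_iter, levels, adjust) {
  P <- transition_matrix(graph)
  f <- refine_density(P, f0, alpha = alpha, tol = tol, max_iter = max_iter)
  modes <- find_modes(graph, f)
  forest <- build_forest(graph, f, modes)
  valleys <- compute_valleys(graph, f, forest)
  tree <- sweep_merge(valleys, forest, f, levels = levels, adjust = adjust)
  list(f = f, forest = forest, valleys = valleys, tree = tree)
}

new_densitycut <- function(graph, f0, stages, data = NULL, call_info = list()) {
  structure(
    c(list(
      graph = graph,
      f0 = f0,
      f = stages$f,
      forest = stages$forest,
      valleys = stages$valleys,
      tree = stages$tree,
      labels = stages$tree$final_labels,
      data = data
    ), call_info),
    class = "densitycut"
  )
}

#' Cluster points by graph-based density mode seeking
#'
#' Runs the full pipeline on a point set: build the exact directed
#' K-nearest-neighbour graph, estimate Knn densities, refine them by a random
#' walk with restart, assign every point to the basin of attraction of a
#' density mode by graph hill climbing, then merge adjacent basins across an
#' even saliency-threshold sweep and keep the most persistent cluster count.
#' No target number of clusters is required.
#'
#' @param data Data frame or numeric matrix; rows are observations, numeric
#'   columns the features. Non-numeric columns and columns named `id` or
#'   `label` (metadata/ground truth, as produced by the `sim_*()` generators)
#'   are ignored.
#' @param k Neighbourhood size; default `round(log2(N))` with floor 3.
#' @param alpha Random-walk damping in `[0, 1]`. Default 0.9.
#' @param levels Number of saliency-sweep intervals. Default 100.
#' @param adjust Apply the valley-height adjustment (default `TRUE`).
#' @param metric `"euclidean"` or `"correlation"`.
#' @param tol,max_iter Convergence controls for [refine_density()].
#' @return A `densitycut` object; see [tidy.densitycut()],
#'   [glance.densitycut()] and [autoplot.densitycut()]. `$labels` holds the
#'   selected clustering (1-based, 0 = outlier).
#' @export
#' @examples
#' pts <- sim_blobs(n = 300, seed = 1)
#' fit <- density_cut(pts)
#' glance(fit)
density_cut <- function(data, k = NULL, alpha = 0.9, levels = 100L,
                        adjust = TRUE, metric = c("euclidean", "correlation"),
                        tol = 1e-9, max_iter = 1000L) {
  metric <- match.arg(metric)
  x <- dc_coords(data)
  graph <- knn_graph(x, k = k, metric = metric)
  f0 <- knn_density(graph)
  stages <- dc_run_stages(graph, f0, alpha, tol, max_iter, levels, adjust)
  new_densitycut(graph, f0, stages, data = x,
                 call_info = list(k = graph$k, alpha = alpha,
                                  levels = levels, adjust = adjust,
                                  metric = metric))
}

#' Cluster a precomputed Knn graph
#'
#' Entry point for data already in graph form. When no initial density is
#' supplied the refinement starts from the uniform vector, which makes the
#' refined density a personalised-PageRank score on the graph.
#'
#' @param graph A `knn_graph` (e.g. from [read_edge_list()] or
#'   [as_knn_graph()]).
#' @param f0 Optional initial density vector (normalised to sum 1 if not
#'   already); default uniform.
#' @inheritParams density_cut
#' @return A `densitycut` object.
#' @export
density_cut_graph <- function(graph, f0 = NULL, alpha = 0.9, levels = 100L,
                              adjust = TRUE, tol = 1e-9, max_iter = 1000L) {
  stopifnot(inherits(graph, "knn_graph"))
  if (is.null(f0)) {
    f0 <- new_dc_density(rep(1 / graph$n_nodes, graph$n_nodes), "initial")
  } else {
    v <- dc_density_values(f0)
    if (any(v < 0) || sum(v) <= 0) {
      dc_abort_parameter("`f0` must be nonnegative with positive sum")
    }
    f0 <- new_dc_density(v / sum(v), "initial")
  }
  stages <- dc_run_stages(graph, f0, alpha, tol, max_iter, levels, adjust)
  new_densitycut(graph, f0, stages, data = NULL,
                 call_info = list(k = graph$k, alpha = alpha,
                                  levels = levels, adjust = adjust,
                                  metric = graph$metric))
}

#' @export
print.densitycut <- function(x, ...) {
  cat(sprintf("<densitycut> %d points, K = %d, alpha = %g, adjust = %s\n",
              x$graph$n_nodes, x$k, x$alpha, x$adjust))
  cat(sprintf("  %d initial mode(s) -> %d selected cluster(s); refinement took %d iteration(s)\n",
              length(x$forest$roots), x$tree$selected_count,
              x$f$iterations_used))
  n_out <- sum(x$labels == 0)
  if (n_out > 0) cat(sprintf("  %d outlier point(s) (label 0)\n", n_out))
  invisible(x)
}

#' Per-point results of a densitycut fit
#'
#' @param x A `densitycut` object.
#' @param ... Unused.
#' @return A tibble with one row per point: `node`, initial and refined
#'   densities (`f0`, `f`), `initial_cluster` (hill-climbing tree) and
#'   `cluster` (selected clustering; 0 = outlier).
#' @export
tidy.densitycut <- function(x, ...) {
  tibble(
    node = seq_len(x$graph$n_nodes),
    f0 = x$f0$values,
    f = x$f$values,
    initial_cluster = x$forest$labels,
    cluster = x$labels
  )
}

#' One-row summary of a densitycut fit
#'
#' @param x A `densitycut` object.
#' @param ... Unused.
#' @return A one-row tibble: problem size, parameters, mode counts, selected
#'   cluster count and refinement iterations.
#' @export
glance.densitycut <- function(x, ...) {
  tibble(
    n = x$graph$n_nodes,
    k = x$k,
    alpha = x$alpha,
    levels = x$levels,
    adjust = x$adjust,
    metric = x$metric,
    n_modes = length(x$forest$modes),
    n_modes_removed = length(x$forest$removed_modes),
    n_initial_clusters = length(x$forest$roots),
    n_clusters = x$tree$selected_count,
    n_outliers = sum(x$labels == 0),
    iterations = x$f$iterations_used,
    converged = x$f$converged
  )
}
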