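# Directed K-nearest-neighbour graphs.
#
# The graph is directed and unweighted: every node points at its K nearest
# other points (out-neighbours, fixed out-degree K), while in-degree varies
# freely -- outliers may have no in-neighbours at all. Both directions are
# stored because mode detection and hill climbing read the in-neighbour
# lists, not the out-neighbour lists.

#' Extract the numeric coordinate matrix from a data frame or matrix
#'
#' Non-numeric columns are dropped, as are columns named `id` or `label`
#' (metadata by convention -- the generators attach ground truth as `label`,
#' and clustering must never see it). This is what lets generator output
#' tibbles flow straight into [density_cut()].
#' @noRd
dc_coords <- function(data) {
  if (is.matrix(data)) {
    if (!is.numeric(data)) dc_abort_parameter("matrix input must be numeric")
    x <- data
  } else if (is.data.frame(data)) {
    num <- vapply(data, is.numeric, logical(1)) &
      !(names(data) %in% c("id", "label"))
    if (!any(num)) dc_abort_parameter("no numeric columns in input data")
    x <- as.matrix(data[num])
  } else {
    dc_abort_parameter("`data` must be a data frame or a numeric matrix")
  }
  if (nrow(x) < 2L) dc_abort_parameter("need at least 2 points")
  if (!all(is.finite(x))) dc_abort_parameter("all coordinates must be finite")
  x
}

#' Default neighbourhood size
#'
#' `round(log2(N))` with a floor of 3, the rule used throughout: large enough
#' to smooth the density estimate, small enough to resolve local maxima.
#'
#' @param n Number of points.
#' @return An integer neighbourhood size.
#' @export
#' @examples
#' default_k(240)  # 8
#' default_k(4096) # 12
default_k <- function(n) {
  max(3L, as.integer(round(log2(n))))
}

new_knn_graph <- function(idx, dist, metric, dim = NA_integer_) {
  n <- nrow(idx)
  k <- ncol(idx)
  src <- rep(seq_len(n), times = k)
  tgt <- as.integer(idx)
  d <- as.numeric(dist)
  o <- order(tgt, src)
  ftgt <- factor(tgt[o], levels = seq_len(n))
  structure(
    list(
      n_nodes = n,
      k = k,
      metric = metric,
      dim = dim,
      idx = idx,
      dist = dist,
      in_nb = unname(split(src[o], ftgt)),
      in_dist = unname(split(d[o], ftgt))
    ),
    class = "knn_graph"
  )
}

#' Build a directed K-nearest-neighbour graph
#'
#' Each point is connected to its `k` nearest *other* points under the chosen
#' metric (exact search; distance ties broken towards the smaller row index so
#' the graph is deterministic). The point itself is never its own neighbour.
#' Duplicate points are allowed and yield zero distances.
#'
#' For `metric = "correlation"` the distance is `1 - cor(x, y)` (Pearson).
#' Rows are standardised once and searched in Euclidean space, using the
#' identity `|a - b|^2 = 2 (1 - cor)` for unit-norm centred rows, so the
#' neighbour sets are exact.
#'
#' @param data Data frame or numeric matrix; rows are observations. Non-numeric
#'   columns are ignored.
#' @param k Out-degree of every node (`1 <= k < N`). Default
#'   [default_k()]`(N)`.
#' @param metric `"euclidean"` (default) or `"correlation"`.
#' @return A `knn_graph` object: out-neighbour index/distance matrices
#'   (`idx`, `dist`, nearest first) and the transposed in-neighbour lists
#'   (`in_nb`, `in_dist`).
#' @export
#' @examples
#' pts <- data.frame(x = c(0, 1, 3))
#' g <- knn_graph(pts, k = 1)
#' g$idx # 0 -> 1, 1 -> 0, 3 -> 1
knn_graph <- function(data, k = NULL, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  x <- dc_coords(data)
  n <- nrow(x)
  if (is.null(k)) k <- default_k(n)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k >= n) {
    dc_abort_parameter(sprintf("`k` must satisfy 1 <= k < N = %d (got %s)",
                               n, paste(k, collapse = ",")))
  }
  if (metric == "correlation") {
    if (ncol(x) < 2L) dc_abort_parameter("correlation metric needs D >= 2")
    xc <- x - rowMeans(x)
    nrm <- sqrt(rowSums(xc^2))
    if (any(nrm == 0)) {
      dc_abort_parameter("correlation metric undefined for constant rows")
    }
    res <- .knn_brute_force(xc / nrm, k)
    # |a-b|^2 = 2(1 - cor)  =>  d_cor = d_euc^2 / 2
    res$dist <- res$dist^2 / 2
  } else {
    res <- .knn_brute_force(x, k)
  }
  new_knn_graph(res$idx, res$dist, metric, dim = ncol(x))
}

#' Assemble a K-nearest-neighbour graph from an edge table
#'
#' @param edges Data frame with integer columns `source`, `target` (1-based
#'   node indices) and numeric `distance`. Every node must have the same
#'   out-degree and no self-edges.
#' @param metric Metric label to record on the graph.
#' @return A `knn_graph`.
#' @export
as_knn_graph <- function(edges, metric = "euclidean") {
  req <- c("source", "target", "distance")
  if (!all(req %in% names(edges))) {
    dc_abort_format("edge table needs columns source, target, distance")
  }
  src <- as.integer(edges$source)
  tgt <- as.integer(edges$target)
  d <- as.numeric(edges$distance)
  if (anyNA(src) || anyNA(tgt) || anyNA(d)) {
    dc_abort_format("edge table contains non-numeric or missing entries")
  }
  if (any(d < 0)) dc_abort_format("edge distances must be nonnegative")
  if (any(src == tgt)) {
    dc_abort_format(sprintf("self-edge at node %d", src[which(src == tgt)[1]]))
  }
  n <- max(src, tgt)
  if (min(src, tgt) < 1L) dc_abort_format("node indices must be >= 1")
  deg <- tabulate(src, nbins = n)
  if (length(unique(deg)) != 1L) {
    bad <- which(deg != stats::median(deg))[1]
    dc_abort_format(sprintf(
      "ragged out-degrees: node %d has out-degree %d, expected %d",
      bad, deg[bad], as.integer(stats::median(deg))))
  }
  k <- deg[1]
  o <- order(src, d, tgt)
  idx <- matrix(tgt[o], nrow = n, ncol = k, byrow = TRUE)
  dist <- matrix(d[o], nrow = n, ncol = k, byrow = TRUE)
  if (anyDuplicated(cbind(src, tgt))) {
    dc_abort_format("duplicate edges in edge table")
  }
  new_knn_graph(idx, dist, metric)
}

#' Read a K-nearest-neighbour graph from an edge-list TSV
#'
#' The file has a header line `source  target  distance` and 0-based node
#' indices, the same format [write_edge_list()] produces.
#'
#' @param path Path to the TSV file.
#' @return A `knn_graph`.
#' @export
read_edge_list <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_integer(),
    target = readr::col_integer(),
    distance = readr::col_double()
  ), progress = FALSE)
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    dc_abort_format(sprintf("malformed edge list at line %d of %s",
                            prob$row[1] + 1L, path))
  }
  as_knn_graph(dplyr::mutate(tab,
                             source = .data$source + 1L,
                             target = .data$target + 1L))
}

#' Write a graph as an edge-list TSV (0-based indices)
#'
#' @param graph A `knn_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  tab <- tidy(graph)
  readr::write_tsv(dplyr::mutate(tab,
                                 source = .data$source - 1L,
                                 target = .data$target - 1L), path)
  invisible(path)
}

#' Row-stochastic transition matrix of a Knn graph
#'
#' Row-normalised adjacency `P = D^-1 W`: each row has exactly `k` entries of
#' `1/k` at that node's out-neighbours, so a step of the random walk moves to
#' a uniformly chosen out-neighbour.
#'
#' @param graph A `knn_graph`.
#' @return A sparse `dgCMatrix` with unit row sums.
#' @export
transition_matrix <- function(graph) {
  stopifnot(inherits(graph, "knn_graph"))
  n <- graph$n_nodes
  k <- graph$k
  Matrix::sparseMatrix(
    i = rep(seq_len(n), times = k),
    j = as.integer(graph$idx),
    x = 1 / k,
    dims = c(n, n)
  )
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("<knn_graph> %d nodes, out-degree K = %d, metric = %s\n",
              x$n_nodes, x$k, x$metric))
  indeg <- lengths(x$in_nb)
  cat(sprintf("  in-degree: min %d, median %g, max %d (%d node(s) with none)\n",
              min(indeg), stats::median(indeg), max(indeg), sum(indeg == 0)))
  invisible(x)
}

#' Tidy a Knn graph into an edge tibble
#'
#' @param x A `knn_graph`.
#' @param ... Unused.
#' @return A tibble with columns `source`, `target`, `rank` (1 = nearest) and
#'   `distance`, one row per directed edge.
#' @export
tidy.knn_graph <- function(x, ...) {
  tibble(
    source = rep(seq_len(x$n_nodes), times = x$k),
    target = as.integer(x$idx),
    rank = rep(seq_len(x$k), each = x$n_nodes),
    distance = as.numeric(x$dist)
  ) |>
    dplyr::arrange(.data$source, .data$rank)
}
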