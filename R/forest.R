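# Mode detection and graph hill climbing.
#
# A mode is a node whose (refined) density exceeds that of every in-neighbour;
# in-neighbours rather than out-neighbours are used so that a small tight
# cluster (fewer than K points, forming a near-clique) can still surface its
# own mode. Candidate modes backed by fewer than K/2 in-neighbours are treated
# as outlier artefacts and removed. Every remaining point climbs to the
# closest in-neighbour of higher density; the resulting forest of parent
# pointers is the initial clustering (one tree per mode).

# Strict total order on densities: u precedes v iff f_u < f_v, ties broken so
# the smaller node index is "higher". rank_of[v] is the position in that
# order; all mode/parent comparisons go through it, making results
# deterministic under exact density ties.
dc_density_rank <- function(f) {
  fv <- dc_density_values(f)
  o <- order(fv, -seq_along(fv))
  r <- integer(length(fv))
  r[o] <- seq_along(fv)
  r
}

#' Detect density modes on a Knn graph
#'
#' Candidate modes are nodes whose density is the largest among all their
#' in-neighbours (nodes with no in-neighbours qualify vacuously). Candidates
#' with in-degree below `ceiling(k / 2)` are filtered into `removed_modes`:
#' they are supported by too few neighbours to be trusted, and their points
#' are absorbed into adjacent trees.
#'
#' @param graph A `knn_graph`.
#' @param f Densities (`dc_density` or numeric vector), usually refined.
#' @param k Neighbourhood size used for the in-degree filter; defaults to the
#'   graph's `k`.
#' @return A list with integer vectors `modes`, `removed_modes`, and
#'   `in_degree`.
#' @export
find_modes <- function(graph, f, k = graph$k) {
  stopifnot(inherits(graph, "knn_graph"))
  r <- dc_density_rank(f)
  n <- graph$n_nodes
  indeg <- lengths(graph$in_nb)
  is_candidate <- vapply(seq_len(n), function(v) {
    nb <- graph$in_nb[[v]]
    length(nb) == 0L || all(r[nb] < r[v])
  }, logical(1))
  cand <- which(is_candidate)
  keep <- indeg[cand] >= ceiling(k / 2)
  list(
    modes = cand[keep],
    removed_modes = cand[!keep],
    in_degree = indeg
  )
}

#' Build the hill-climbing forest (initial clustering)
#'
#' Every non-mode node is attached to the in-neighbour of higher density that
#' is closest by edge distance (distance ties to the smaller node index).
#' A removed candidate mode has no higher in-neighbour, so it attaches to its
#' nearest *out*-neighbour of higher density instead; if none exists either,
#' it stays a provisional root and its tree is flagged for force-merging
#' during the hierarchy sweep. Density strictly increases along every parent
#' chain, so the structure is an acyclic forest rooted at the modes.
#'
#' @param graph A `knn_graph`.
#' @param f Densities (`dc_density` or numeric), usually refined.
#' @param modes Optional result of [find_modes()]; computed if missing.
#' @return A `dc_forest`: `parent` (NA at roots), `modes`, `removed_modes`,
#'   `labels` (initial tree index per node, 1..T), `roots` (root node per
#'   tree) and `outlier_trees` (tree indices rooted at provisional,
#'   filtered-out modes).
#' @export
build_forest <- function(graph, f, modes = NULL) {
  stopifnot(inherits(graph, "knn_graph"))
  if (is.null(modes)) modes <- find_modes(graph, f)
  r <- dc_density_rank(f)
  n <- graph$n_nodes
  mode_set <- modes$modes
  if (length(mode_set) == 0L) {
    warn("no modes survive the in-degree filter; falling back to the single highest-density node",
         class = "dc_no_modes_warning")
    mode_set <- which.max(r)
  }
  is_mode <- rep(FALSE, n)
  is_mode[mode_set] <- TRUE

  parent <- rep(NA_integer_, n)
  provisional <- logical(n)
  for (v in seq_len(n)) {
    if (is_mode[v]) next
    nb <- graph$in_nb[[v]]
    higher <- nb[r[nb] > r[v]]
    if (length(higher) > 0L) {
      d <- graph$in_dist[[v]][r[nb] > r[v]]
      parent[v] <- higher[order(d, higher)][1L]
    } else {
      # removed candidate mode (or isolated local max): climb out-edges
      out <- graph$idx[v, ]
      ok <- which(r[out] > r[v])
      if (length(ok) > 0L) {
        parent[v] <- out[ok[1L]] # out list already ordered by (dist, index)
      } else {
        provisional[v] <- TRUE # flagged outlier root
      }
    }
  }

  roots_nodes <- sort(c(mode_set, which(provisional)))
  tree_of_root <- setNames(seq_along(roots_nodes), roots_nodes)
  labels <- rep(NA_integer_, n)
  labels[roots_nodes] <- seq_along(roots_nodes)
  # parents always have higher rank, so a sweep in decreasing rank resolves
  # every label in one pass
  for (v in order(r, decreasing = TRUE)) {
    if (is.na(labels[v])) labels[v] <- labels[parent[v]]
  }

  structure(
    list(
      parent = parent,
      modes = mode_set,
      removed_modes = modes$removed_modes,
      labels = labels,
      roots = roots_nodes,
      outlier_trees = unname(tree_of_root[as.character(which(provisional))])
    ),
    class = "dc_forest"
  )
}

#' @export
print.dc_forest <- function(x, ...) {
  cat(sprintf("<dc_forest> %d nodes in %d trees (%d mode(s), %d candidate(s) filtered, %d outlier tree(s))\n",
              length(x$labels), length(x$roots), length(x$modes),
              length(x$removed_modes), length(x$outlier_trees)))
  invisible(x)
}

#' Tidy a forest into a per-node tibble
#'
#' @param x A `dc_forest`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `parent` (NA at roots),
#'   `initial_cluster` and `is_mode`.
#' @export
tidy.dc_forest <- function(x, ...) {
  tibble(
    node = seq_along(x$labels),
    parent = x$parent,
    initial_cluster = x$labels,
    is_mode = seq_along(x$labels) %in% x$modes
  )
}
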