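# Saliency-indexed hierarchical merging and stable cluster-number selection.
#
# Two adjacent trees are separated by a "valley": the boundary nodes that have
# a higher-density in-neighbour in the other tree. The valley height (max
# density over the valley nodes) relative to the shorter tree's height is the
# saliency index nu in [0, 1] -- scale-free, so multiplying all densities by a
# constant changes nothing. Sweeping the merge threshold evenly from 1 down to
# 0 gives a nested hierarchy; the cluster count that persists over the most
# threshold levels is selected as the stable clustering.

#' Valley-height adjustment
#'
#' Inflates a valley height by the fraction of nodes with density strictly
#' below it: `(1 + #\{i : f_i < h\} / N) * h`. A deep valley inside a
#' high-density region gets pushed up (most points lie below it), smoothing
#' spurious splits of dense clusters; the factor is always in `[1, 2]`.
#'
#' @param h_valley Valley height(s), nonnegative; vectorised.
#' @param f Densities over all nodes (`dc_density` or numeric vector).
#' @return Adjusted height(s).
#' @export
#' @examples
#' adjust_valley(0.25, c(0.1, 0.2, 0.3, 0.4)) # (1 + 2/4) * 0.25 = 0.375
adjust_valley <- function(h_valley, f) {
  fv <- dc_density_values(f)
  frac <- vapply(h_valley, function(h) sum(fv < h), numeric(1)) / length(fv)
  (1 + frac) * h_valley
}

#' Saliency index of a valley
#'
#' `nu = h / min(h_Ta, h_Tb)`, clipped to `[0, 1]` (the adjusted height can
#' exceed the shorter tree). Vectorised over records.
#'
#' @param h_valley Valley height (adjusted or not).
#' @param h_tree_a,h_tree_b Heights (root densities) of the two trees.
#' @return Saliency in `[0, 1]`.
#' @export
saliency_index <- function(h_valley, h_tree_a, h_tree_b) {
  pmin(1, h_valley / pmin(h_tree_a, h_tree_b))
}

#' Valleys between adjacent trees of a forest
#'
#' Every edge joining two trees contributes its lower-density endpoint as a
#' boundary (valley) node of that endpoint's tree; the valley of an unordered
#' tree pair is the union of its two boundary sets, and its height is the
#' maximum density over the valley nodes. Edges are considered in both
#' directions: boundary points sit in low-density terrain, so their links
#' into the neighbouring tree are typically *out*-edges (their in-vertices
#' come from sparser regions still), and restricting the boundary test to
#' in-edges alone would leave adjacent basins without a valley on sparse
#' graphs. Tree pairs with no connecting edge at all have no record and
#' never merge.
#'
#' @param graph A `knn_graph`.
#' @param f Densities (`dc_density` or numeric), usually refined.
#' @param forest A `dc_forest`.
#' @return A tibble with one row per adjacent tree pair: `tree_a < tree_b`,
#'   list-column `valley_nodes`, `h_valley`, `h_adjusted`, tree heights and
#'   `saliency` / `saliency_adjusted`.
#' @export
compute_valleys <- function(graph, f, forest) {
  stopifnot(inherits(graph, "knn_graph"), inherits(forest, "dc_forest"))
  fv <- dc_density_values(f)
  r <- dc_density_rank(fv)
  lab <- forest$labels
  n <- graph$n_nodes
  src <- rep(seq_len(n), times = graph$k)
  tgt <- as.integer(graph$idx)
  keep <- lab[src] != lab[tgt]
  heights <- fv[forest$roots]
  if (!any(keep)) {
    return(tibble(tree_a = integer(), tree_b = integer(),
                  valley_nodes = list(), h_valley = numeric(),
                  h_adjusted = numeric(), h_tree_a = numeric(),
                  h_tree_b = numeric(), saliency = numeric(),
                  saliency_adjusted = numeric()))
  }

  rec <- tibble(
    tree_a = pmin(lab[src[keep]], lab[tgt[keep]]),
    tree_b = pmax(lab[src[keep]], lab[tgt[keep]]),
    # the lower-density endpoint of each crossing edge is the valley node
    node = ifelse(r[tgt[keep]] < r[src[keep]], tgt[keep], src[keep])
  ) |>
    dplyr::distinct() |>
    dplyr::group_by(.data$tree_a, .data$tree_b) |>
    dplyr::summarise(
      valley_nodes = list(sort(unique(.data$node))),
      h_valley = max(fv[.data$node]),
      .groups = "drop"
    )
  rec |>
    dplyr::mutate(
      h_adjusted = adjust_valley(.data$h_valley, fv),
      h_tree_a = heights[.data$tree_a],
      h_tree_b = heights[.data$tree_b],
      saliency = saliency_index(.data$h_valley, .data$h_tree_a, .data$h_tree_b),
      saliency_adjusted = saliency_index(.data$h_adjusted, .data$h_tree_a,
                                         .data$h_tree_b)
    )
}

# internal: union-find over initial trees
dc_uf_find <- function(up, i) {
  while (up[i] != i) i <- up[i]
  i
}

#' Sweep the saliency threshold and select the stable clustering
#'
#' Thresholds `nu_l = 1 - l/L` for `l = 0..L` are visited in order. At each
#' level the adjacent pair with the highest current saliency is merged while
#' that saliency exceeds `nu_l`; after a merge the combined tree's height is
#' the max of the two, valley node-sets towards third trees are unioned, and
#' valley heights, adjustments and saliencies are recomputed before the next
#' pick. Trees flagged as outliers by [build_forest()] are force-merged into
#' their most salient neighbour before the sweep (or dropped to label 0 when
#' they have no neighbour). The cluster count persisting over the most levels
#' wins; frequency ties go to the smaller (coarser) count.
#'
#' @param valleys Valley tibble from [compute_valleys()].
#' @param forest The `dc_forest` the valleys were computed on.
#' @param f Densities used throughout (`dc_density` or numeric).
#' @param levels Number of sweep intervals L (>= 10); `L + 1` thresholds.
#'   Default 100.
#' @param adjust Use adjusted valley heights (default `TRUE`).
#' @return A `dc_merge_tree`: `thresholds`, `counts_per_level`, `merges`
#'   (tibble: level threshold, trees, saliency), `frequency` (tibble),
#'   `selected_count`, `final_labels` (1-based clusters, 0 = outlier) and
#'   `partitions` (per-node labels at every distinct count).
#' @export
sweep_merge <- function(valleys, forest, f, levels = 100L, adjust = TRUE) {
  stopifnot(inherits(forest, "dc_forest"))
  if (levels < 10L) dc_abort_parameter("`levels` must be >= 10")
  fv <- dc_density_values(f)
  n_tree <- length(forest$roots)
  heights <- fv[forest$roots]
  sal_col <- if (adjust) "saliency_adjusted" else "saliency"

  # mutable pair store keyed "a:b" with a < b over current representatives
  pairs <- new.env(parent = emptyenv())
  pkey <- function(a, b) paste0(min(a, b), ":", max(a, b))
  pset <- function(a, b, nodes) {
    h <- max(fv[nodes])
    ha <- if (adjust) adjust_valley(h, fv) else h
    assign(pkey(a, b),
           list(a = min(a, b), b = max(a, b), nodes = nodes,
                sal = saliency_index(ha, heights[a], heights[b])),
           envir = pairs)
  }
  if (nrow(valleys) > 0) {
    for (i in seq_len(nrow(valleys))) {
      pset(valleys$tree_a[i], valleys$tree_b[i], valleys$valley_nodes[[i]])
    }
  }

  up <- seq_len(n_tree)
  active <- rep(TRUE, n_tree)
  dropped <- rep(FALSE, n_tree)
  merges <- list()

  best_pair <- function() {
    ks <- ls(pairs)
    if (length(ks) == 0L) return(NULL)
    recs <- lapply(ks, get, envir = pairs)
    sal <- vapply(recs, `[[`, numeric(1), "sal")
    a <- vapply(recs, `[[`, numeric(1), "a")
    b <- vapply(recs, `[[`, numeric(1), "b")
    recs[[order(-sal, a, b)[1L]]]
  }

  do_merge <- function(a, b, sal, threshold) {
    keep <- min(a, b)
    drop <- max(a, b)
    rm(list = pkey(a, b), envir = pairs)
    heights[keep] <<- max(heights[a], heights[b])
    up[drop] <<- keep
    active[drop] <<- FALSE
    merges[[length(merges) + 1L]] <<-
      tibble(threshold = threshold, tree_a = a, tree_b = b, saliency = sal)
    # re-route pairs that referenced `drop`
    for (key in ls(pairs)) {
      rec <- get(key, envir = pairs)
      if (rec$a == drop || rec$b == drop) {
        other <- if (rec$a == drop) rec$b else rec$a
        rm(list = key, envir = pairs)
        if (other == keep) next
        prev_key <- pkey(keep, other)
        nodes <- rec$nodes
        if (exists(prev_key, envir = pairs)) {
          nodes <- sort(unique(c(nodes, get(prev_key, envir = pairs)$nodes)))
        }
        pset(keep, other, nodes)
      } else if (rec$a == keep || rec$b == keep) {
        # height of `keep` changed: recompute saliency
        pset(rec$a, rec$b, rec$nodes)
      }
    }
  }

  # force-merge flagged outlier trees before the sweep
  for (t in forest$outlier_trees) {
    rep_t <- dc_uf_find(up, t)
    if (!active[rep_t] || dropped[rep_t]) next
    ks <- ls(pairs)
    recs <- lapply(ks, get, envir = pairs)
    inv <- recs[vapply(recs, function(r) r$a == rep_t || r$b == rep_t,
                       logical(1))]
    if (length(inv) == 0L) {
      dropped[rep_t] <- TRUE
      active[rep_t] <- FALSE
    } else {
      sal <- vapply(inv, `[[`, numeric(1), "sal")
      best <- inv[[which.max(sal)]]
      do_merge(best$a, best$b, best$sal, threshold = NA_real_)
    }
  }

  thresholds <- 1 - (0:levels) / levels
  counts <- integer(levels + 1L)
  partitions <- list()
  snapshot <- function(count) {
    key <- as.character(count)
    if (!is.null(partitions[[key]])) return()
    reps <- vapply(seq_len(n_tree), function(t) dc_uf_find(up, t), integer(1))
    reps[dropped[reps]] <- 0L
    live <- sort(unique(reps[reps > 0L]))
    relab <- integer(max(c(1L, live)))
    relab[live] <- seq_along(live)
    node_lab <- ifelse(reps[forest$labels] == 0L, 0L,
                       relab[pmax(reps[forest$labels], 1L)])
    partitions[[key]] <<- as.integer(node_lab)
  }

  for (l in 0:levels) {
    nu <- thresholds[l + 1L]
    repeat {
      rec <- best_pair()
      if (is.null(rec) || rec$sal <= nu) break
      do_merge(rec$a, rec$b, rec$sal, threshold = nu)
    }
    counts[l + 1L] <- sum(active)
    snapshot(counts[l + 1L])
  }

  freq <- table(counts)
  freq_tbl <- tibble(
    count = as.integer(names(freq)),
    frequency = as.integer(freq)
  ) |> dplyr::arrange(.data$count)
  selected <- freq_tbl$count[freq_tbl$frequency == max(freq_tbl$frequency)][1L]

  structure(
    list(
      thresholds = thresholds,
      counts_per_level = counts,
      merges = if (length(merges)) dplyr::bind_rows(merges) else
        tibble(threshold = numeric(), tree_a = integer(),
               tree_b = integer(), saliency = numeric()),
      frequency = freq_tbl,
      selected_count = selected,
      final_labels = partitions[[as.character(selected)]],
      partitions = partitions,
      adjust = adjust,
      levels = levels
    ),
    class = "dc_merge_tree"
  )
}

#' @export
print.dc_merge_tree <- function(x, ...) {
  cat(sprintf("<dc_merge_tree> sweep of %d thresholds (adjust = %s)\n",
              length(x$thresholds), x$adjust))
  cat(sprintf("  cluster counts: %d (nu = 1) -> %d (nu = 0); selected %d clusters\n",
              x$counts_per_level[1], x$counts_per_level[length(x$counts_per_level)],
              x$selected_count))
  invisible(x)
}

#' Tidy a merge tree into the per-level sweep table
#'
#' @param x A `dc_merge_tree`.
#' @param ... Unused.
#' @return A tibble with columns `threshold` and `n_clusters`.
#' @export
tidy.dc_merge_tree <- function(x, ...) {
  tibble(threshold = x$thresholds, n_clusters = x$counts_per_level)
}
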