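# The 6-node two-tree fixture used throughout: a 1-D chain 0..5 (k = 2) with
# supplied densities giving modes at nodes 1 and 5, trees {1,2,3,4} (node 4
# climbs to node 3: distance ties break to the smaller index) and {5,6}, and
# a single valley node 4 (via the cross edge 5 -> 4).
fixture_two_trees <- function() {
  g <- knn_graph(data.frame(x = 0:5), k = 2)
  f <- c(0.30, 0.22, 0.06, 0.05, 0.28, 0.03)
  f <- f / sum(f)
  forest <- build_forest(g, f)
  list(g = g, f = f, forest = forest)
}

test_that("valley-height adjustment matches the counting formula", {
  f <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(adjust_valley(0.25, f), (1 + 2 / 4) * 0.25) # = 0.375
  expect_equal(adjust_valley(0.05, f), 0.05)  # below every density: factor 1
  expect_equal(adjust_valley(0.5, f), 1.0)    # above every density: factor 2
  expect_equal(adjust_valley(c(0.25, 0.05), f), c(0.375, 0.05))
})

test_that("saliency index is the clipped valley/tree-height ratio", {
  expect_equal(saliency_index(0.2, 0.5, 0.2), 1)   # h = min tree height
  expect_equal(saliency_index(0.1, 0.5, 0.4), 0.25)
  expect_equal(saliency_index(0.9, 0.5, 0.4), 1)   # clipped
  # invariance under scaling all densities
  c_ <- 37.5
  expect_equal(saliency_index(0.1 * c_, 0.5 * c_, 0.4 * c_), 0.25)
})

test_that("valleys on the hand-built two-tree fixture match manual Eqs", {
  fx <- fixture_two_trees()
  expect_equal(sort(unique(fx$forest$labels)), c(1L, 2L))
  v <- compute_valleys(fx$g, fx$f, fx$forest)
  expect_equal(nrow(v), 1L)
  # crossing edges 4<->5 and 6->4; their lower-density endpoints are 4 and 6
  expect_equal(v$valley_nodes[[1]], c(4L, 6L))
  s <- sum(c(0.30, 0.22, 0.06, 0.05, 0.28, 0.03))
  expect_equal(v$h_valley, 0.05 / s, tolerance = 1e-12)
  # one density (node 6) lies strictly below the valley: factor 1 + 1/6
  expect_equal(v$h_adjusted, (1 + 1 / 6) * 0.05 / s, tolerance = 1e-12)
  expect_equal(v$h_tree_a, 0.30 / s)
  expect_equal(v$h_tree_b, 0.28 / s)
  expect_equal(v$saliency, 0.05 / 0.28, tolerance = 1e-12)
  expect_equal(v$saliency_adjusted, (7 / 6) * 0.05 / 0.28, tolerance = 1e-12)
})

test_that("valley records equal a brute-force edge scan on random inputs", {
  for (seed in 1:4) {
    g <- rand_graph(30, 4, seed = seed)
    f <- rand_density(30, seed = seed + 7)
    forest <- build_forest(g, f)
    v <- compute_valleys(g, f, forest)
    # oracle: scan every directed edge independently; the lower-density
    # endpoint (ties to the larger index) is the valley node of the pair
    lab <- forest$labels
    denser <- function(u, w) f[u] > f[w] || (f[u] == f[w] && u < w)
    valley <- list()
    for (u in 1:30) {
      for (w in g$idx[u, ]) {
        if (lab[u] != lab[w]) {
          key <- paste(min(lab[u], lab[w]), max(lab[u], lab[w]))
          low <- if (denser(u, w)) w else u
          valley[[key]] <- sort(unique(c(valley[[key]], low)))
        }
      }
    }
    expect_equal(nrow(v), length(valley))
    for (i in seq_len(nrow(v))) {
      key <- paste(v$tree_a[i], v$tree_b[i])
      expect_equal(v$valley_nodes[[i]], valley[[key]])
      expect_equal(v$h_valley[i], max(f[valley[[key]]]))
    }
  }
})

test_that("trees without cross edges never merge", {
  pts <- sim_blobs(n = 300, sep = 50, seed = 12) # graph surely disconnected
  fit <- density_cut(pts)
  v <- fit$valleys
  lab <- fit$forest$labels
  blob_of_tree <- vapply(seq_along(fit$forest$roots), function(t)
    unique(pts$label[lab == t])[1], integer(1))
  # no valley record joins trees from different blobs
  if (nrow(v) > 0) {
    expect_true(all(blob_of_tree[v$tree_a] == blob_of_tree[v$tree_b]))
  }
  # and the final sweep keeps the components separate down to nu = 0
  expect_equal(fit$tree$counts_per_level[length(fit$tree$thresholds)], 2L)
})

test_that("the sweep grid has L + 1 thresholds from 1 to 0", {
  fx <- fixture_two_trees()
  tr <- sweep_merge(compute_valleys(fx$g, fx$f, fx$forest), fx$forest, fx$f,
                    levels = 100)
  expect_length(tr$thresholds, 101L)
  expect_equal(tr$thresholds[1], 1)
  expect_equal(tr$thresholds[101], 0)
  expect_error(sweep_merge(compute_valleys(fx$g, fx$f, fx$forest),
                           fx$forest, fx$f, levels = 5),
               class = "dc_parameter_error")
})

test_that("two trees merge exactly when the threshold drops below saliency", {
  fx <- fixture_two_trees()
  v <- compute_valleys(fx$g, fx$f, fx$forest)
  for (adj in c(TRUE, FALSE)) {
    tr <- sweep_merge(v, fx$forest, fx$f, levels = 100, adjust = adj)
    sal <- if (adj) v$saliency_adjusted else v$saliency
    expect_equal(nrow(tr$merges), 1L)
    expect_equal(tr$merges$saliency, sal, tolerance = 1e-12)
    # merge is recorded at the first grid threshold strictly below saliency
    expect_equal(tr$merges$threshold, max(tr$thresholds[tr$thresholds < sal]))
    # counts: 2 clusters while threshold >= saliency, then 1
    expect_equal(tr$counts_per_level,
                 ifelse(tr$thresholds >= sal, 2L, 1L))
  }
})

test_that("adjustment can only raise the merge saliency", {
  fx <- fixture_two_trees()
  v <- compute_valleys(fx$g, fx$f, fx$forest)
  expect_true(all(v$saliency_adjusted >= v$saliency))
  tr_off <- sweep_merge(v, fx$forest, fx$f, adjust = FALSE)
  tr_on <- sweep_merge(v, fx$forest, fx$f, adjust = TRUE)
  expect_gt(tr_on$merges$saliency, tr_off$merges$saliency)
})

test_that("counts are non-increasing and partitions nested along the sweep", {
  pts <- sim_gaussian_grid(components = 9, n = 900, sep = 6, seed = 23)
  fit <- density_cut(pts)
  tr <- fit$tree
  expect_true(all(diff(tr$counts_per_level) <= 0))
  counts <- sort(unique(tr$counts_per_level), decreasing = TRUE)
  for (i in seq_along(counts)[-1]) {
    fine <- tr$partitions[[as.character(counts[i - 1])]]
    coarse <- tr$partitions[[as.character(counts[i])]]
    expect_true(is_nested(fine, coarse))
  }
  # selected count is the most frequent, ties to the smaller count
  freq <- tr$frequency
  best <- max(freq$frequency)
  expect_equal(tr$selected_count, min(freq$count[freq$frequency == best]))
})

test_that("the sweep is scale-invariant and deterministic", {
  fx <- fixture_two_trees()
  pts <- sim_gaussian_grid(components = 4, n = 400, sep = 5, seed = 3)
  g <- knn_graph(pts)
  f <- refine_density(transition_matrix(g), knn_density(g))$values
  forest <- build_forest(g, f)
  base <- sweep_merge(compute_valleys(g, f, forest), forest, f)
  for (c_ in withr::with_seed(1, runif(3, 0.01, 50))) {
    scaled <- sweep_merge(compute_valleys(g, f * c_, forest), forest, f * c_)
    expect_identical(scaled$final_labels, base$final_labels)
    expect_identical(scaled$counts_per_level, base$counts_per_level)
    expect_equal(scaled$merges$saliency, base$merges$saliency,
                 tolerance = 1e-9)
  }
  again <- sweep_merge(compute_valleys(g, f, forest), forest, f)
  expect_identical(again$final_labels, base$final_labels)
  expect_identical(again$merges, base$merges)
})

test_that("a single initial tree gives the trivial merge tree", {
  pts <- withr::with_seed(2, data.frame(x = rnorm(80), y = rnorm(80)))
  fit <- density_cut(pts)
  if (length(fit$forest$roots) == 1L) {
    expect_equal(fit$tree$selected_count, 1L)
    expect_equal(nrow(fit$tree$merges), 0L)
  }
  expect_equal(fit$tree$selected_count, 1L)
  expect_equal(unique(fit$labels), 1L)
})

test_that("frequency argmax selection behaves on a constructed profile", {
  # adjacent blobs with spurious sub-modes: several clusters briefly, then a
  # long 2-cluster plateau, then 1 near nu = 0
  pts <- sim_blobs(n = 500, sep = 5, seed = 41)
  fit <- density_cut(pts)
  tr <- fit$tree
  expect_equal(tr$selected_count, 2L)
  freq2 <- tr$frequency$frequency[tr$frequency$count == 2L]
  expect_gt(freq2, max(tr$frequency$frequency[tr$frequency$count != 2L]))
})
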