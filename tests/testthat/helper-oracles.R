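# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive quantities by brute force (O(N^2) scans, exhaustive
# enumeration, dense linear algebra) so they share no code with the package
# internals they check.

# Exact KNN by full pairwise distance sort, ties to the smaller index.
oracle_knn <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    o <- cand[order(d[i, cand], cand)]
    idx[i, ] <- o[seq_len(k)]
    dst[i, ] <- d[i, o[seq_len(k)]]
  }
  list(idx = idx, dist = dst)
}

# Random directed graph with constant out-degree k and random positive edge
# distances (not geometrically realisable; exercises the graph-only paths).
rand_graph <- function(n, k, seed) {
  withr::with_seed(seed, {
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(source = i,
                 target = sample(setdiff(seq_len(n), i), k),
                 distance = runif(k, 0.1, 2))
    }))
    as_knn_graph(edges)
  })
}

rand_density <- function(n, seed) {
  withr::with_seed(seed, {
    f <- runif(n, 0.01, 1)
    f / sum(f)
  })
}

# Mode predicate evaluated straight from the edge table: v is a candidate iff
# every in-neighbour has strictly lower density (ties: the smaller index is
# treated as the denser node); candidates with in-degree < ceiling(k/2) are
# filtered out.
oracle_modes <- function(graph, f, k = graph$k) {
  n <- graph$n_nodes
  edges <- cbind(rep(seq_len(n), times = graph$k), as.integer(graph$idx))
  denser <- function(u, v) f[u] > f[v] || (f[u] == f[v] && u < v)
  cand <- logical(n)
  indeg <- integer(n)
  for (v in seq_len(n)) {
    inn <- edges[edges[, 2] == v, 1]
    indeg[v] <- length(inn)
    cand[v] <- all(vapply(inn, function(u) denser(v, u), logical(1)))
  }
  list(modes = which(cand & indeg >= ceiling(k / 2)),
       removed_modes = which(cand & indeg < ceiling(k / 2)))
}

# Exhaustive maximum-weight one-to-one matching over a contingency table.
oracle_mmm <- function(pred, truth) {
  tab <- unclass(table(factor(pred), factor(truth)))
  nr <- nrow(tab)
  nc <- ncol(tab)
  best <- 0
  recurse <- function(row, used, acc) {
    if (row > nr) {
      best <<- max(best, acc)
      return()
    }
    recurse(row + 1L, used, acc) # leave this cluster unmatched
    for (j in seq_len(nc)) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(row + 1L, used, acc + tab[row, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nc), 0)
  best / sum(tab)
}

# Per-point silhouette widths from the textbook formula.
oracle_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(nrow(x)) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    if (sum(own) == 1) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# Does `fine` refine `coarse` (every fine cluster inside one coarse cluster)?
is_nested <- function(fine, coarse) {
  all(vapply(split(coarse, fine), function(v) length(unique(v)) == 1L,
             logical(1)))
}
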