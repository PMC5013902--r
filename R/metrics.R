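# External clustering validation indices.
#
# All three indices compare a predicted partition with a reference partition
# through their contingency table and are invariant to relabelling. Predicted
# outlier labels (0 or NA) are excluded from the comparison by default, as is
# conventional when the clustering method itself sets points aside.

dc_label_pairs <- function(pred, truth, drop_outliers = TRUE) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    dc_abort_parameter("`pred` and `truth` must have equal positive length")
  }
  keep <- !(is.na(pred) | is.na(truth))
  if (drop_outliers) keep <- keep & !(pred %in% 0) & !(truth %in% 0)
  list(pred = pred[keep], truth = truth[keep])
}

dc_contingency <- function(pred, truth) {
  table(factor(pred), factor(truth))
}

#' Maximum-matching measure
#'
#' Finds the maximum-weight one-to-one assignment between predicted clusters
#' and reference classes over the contingency table (solved as a weighted
#' bipartite matching; rectangular tables are handled by leaving surplus
#' clusters unmatched) and returns the matched mass divided by the number of
#' points. Range `[0, 1]`; 1 iff the partitions are identical up to
#' relabelling.
#'
#' @param pred,truth Label vectors of equal length.
#' @param drop_outliers Drop points whose label is 0 or NA (default `TRUE`).
#' @return A number in `[0, 1]`.
#' @export
cluster_mmm <- function(pred, truth, drop_outliers = TRUE) {
  lp <- dc_label_pairs(pred, truth, drop_outliers)
  tab <- dc_contingency(lp$pred, lp$truth)
  n <- sum(tab)
  nr <- nrow(tab)
  nc <- ncol(tab)
  pos <- which(tab > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(0)
  g <- igraph::make_bipartite_graph(
    c(rep(TRUE, nr), rep(FALSE, nc)),
    edges = as.integer(t(cbind(pos[, 1], nr + pos[, 2])))
  )
  m <- igraph::max_bipartite_match(g, weights = tab[pos])
  m$matching_weight / n
}

#' Normalized mutual information
#'
#' `NMI = I(pred; truth) / norm(H(pred), H(truth))` computed from the
#' contingency table, with the geometric mean as the default normaliser
#' (`"min"`, `"max"` and `"arithmetic"` are available). When both partitions
#' are trivial (zero entropy) the value is 1; when only one is, 0.
#'
#' @inheritParams cluster_mmm
#' @param normalization One of `"geometric"`, `"min"`, `"max"`,
#'   `"arithmetic"`.
#' @return A number in `[0, 1]`.
#' @export
cluster_nmi <- function(pred, truth, drop_outliers = TRUE,
                        normalization = c("geometric", "min", "max",
                                          "arithmetic")) {
  normalization <- match.arg(normalization)
  lp <- dc_label_pairs(pred, truth, drop_outliers)
  tab <- dc_contingency(lp$pred, lp$truth)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  hx <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hy <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  denom <- switch(normalization,
    geometric = sqrt(hx * hy),
    min = min(hx, hy),
    max = max(hx, hy),
    arithmetic = (hx + hy) / 2
  )
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance under the permutation model: expectation 0
#' for independent labelings, maximum 1 for identical partitions.
#'
#' @inheritParams cluster_mmm
#' @return A number `<= 1` (can be slightly negative).
#' @export
cluster_ari <- function(pred, truth, drop_outliers = TRUE) {
  lp <- dc_label_pairs(pred, truth, drop_outliers)
  tab <- dc_contingency(lp$pred, lp$truth)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(if (sum_ij == max_index) 1 else 0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Mean silhouette width
#'
#' Average silhouette over all points under Euclidean distances, delegating
#' the per-point widths to [cluster::silhouette()].
#'
#' @param data Data frame or numeric matrix of coordinates (non-numeric
#'   columns ignored).
#' @param labels Cluster labels; 0/NA entries are dropped first.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_mean <- function(data, labels) {
  x <- dc_coords(data)
  keep <- !is.na(labels) & labels != 0
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2L) {
    dc_abort_parameter("silhouette needs at least 2 clusters")
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(x))
  mean(sil[, "sil_width"])
}

#' All validation indices at once
#'
#' @inheritParams cluster_mmm
#' @return A one-row tibble with columns `mmm`, `nmi`, `ari` and `n` (points
#'   compared after outlier exclusion).
#' @export
cluster_metrics <- function(pred, truth, drop_outliers = TRUE) {
  lp <- dc_label_pairs(pred, truth, drop_outliers)
  tibble(
    mmm = cluster_mmm(pred, truth, drop_outliers),
    nmi = cluster_nmi(pred, truth, drop_outliers),
    ari = cluster_ari(pred, truth, drop_outliers),
    n = length(lp$pred)
  )
}
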