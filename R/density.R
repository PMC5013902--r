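# Density estimation on the Knn graph.
#
# Stage 1: the classical Knn density estimate f0_i = (K-1) / (N V_D r_K^D),
# where V_D is the volume of the D-dimensional unit ball and r_K the distance
# to the Kth nearest neighbour. Stage 2: a random walk with restart on the
# graph smooths f0 -- a node is dense if it is a near neighbour of many nodes
# and its in-neighbours are themselves dense.

new_dc_density <- function(values, stage, alpha = NA_real_,
                           iterations_used = 0L, converged = NA) {
  structure(
    list(values = values, stage = stage, alpha = alpha,
         iterations_used = iterations_used, converged = converged),
    class = "dc_density"
  )
}

dc_density_values <- function(f) {
  if (inherits(f, "dc_density")) f$values else as.numeric(f)
}

#' @export
print.dc_density <- function(x, ...) {
  cat(sprintf("<dc_density> %s densities for %d nodes (sum = %.6g)\n",
              x$stage, length(x$values), sum(x$values)))
  if (x$stage == "refined") {
    cat(sprintf("  alpha = %g, iterations = %d, converged = %s\n",
                x$alpha, x$iterations_used, x$converged))
  }
  invisible(x)
}

#' K-nearest-neighbour density estimate
#'
#' Computes `f0_i = (K-1) / (N * V_D * r_K(x_i)^D)` at every node, with
#' `V_D = pi^(D/2) / Gamma(D/2 + 1)` the unit-ball volume and `r_K` the
#' distance to the Kth nearest other point. Evaluation is in log space
#' (`-D log r_K` can overflow for D in the hundreds) and the vector is
#' normalised to sum 1 by log-sum-exp, so only density *ratios* matter
#' downstream -- which is all the saliency index uses.
#'
#' Duplicate points give `r_K = 0`; those nodes are assigned half the smallest
#' strictly positive `r_K` in the dataset, keeping them the densest nodes
#' without infinities.
#'
#' @param graph A `knn_graph` carrying out-neighbour distances.
#' @param dim Dimensionality D used in the volume term. Defaults to the
#'   dimensionality the graph was built from.
#' @param normalize If `TRUE` (default) return a probability vector; if
#'   `FALSE` return raw estimator values (which vanish for `k = 1`).
#' @return A `dc_density` with `stage = "initial"`.
#' @export
#' @examples
#' g <- knn_graph(data.frame(x = c(0, 1, 3)), k = 2)
#' knn_density(g)$values # (2/7, 3/7, 2/7)
knn_density <- function(graph, dim = NULL, normalize = TRUE) {
  stopifnot(inherits(graph, "knn_graph"))
  if (is.null(dim)) dim <- graph$dim
  if (is.na(dim) || dim < 1) {
    dc_abort_parameter("`dim` must be >= 1 (graph carries no dimensionality)")
  }
  n <- graph$n_nodes
  k <- graph$k
  rk <- graph$dist[, k]
  if (all(rk == 0)) {
    dc_abort_degenerate("all points are identical: every r_K is zero")
  }
  rk[rk == 0] <- min(rk[rk > 0]) / 2
  log_vd <- (dim / 2) * log(pi) - lgamma(dim / 2 + 1)
  log_f <- -dim * log(rk)
  if (normalize) {
    m <- max(log_f)
    vals <- exp(log_f - m - log(sum(exp(log_f - m))))
  } else {
    vals <- exp(log(pmax(k - 1, 0)) - log(n) - log_vd + log_f)
  }
  new_dc_density(vals, stage = "initial")
}

#' Refine densities by a random walk with restart
#'
#' Iterates `f_j^(t+1) = alpha * sum_i P_ij f_i^t + (1 - alpha) * f_j^0` until
#' the max-abs change drops below `tol` or `max_iter` is hit. For
#' `alpha < 1` the fixed point is the closed form
#' `f = (1 - alpha) f0 (I - alpha P)^-1`; at `alpha = 1` the iterate heads for
#' the leading left eigenvector of `P` and may stop at `max_iter` with a
#' warning. Each iteration preserves the unit sum of `f`.
#'
#' @param P Row-stochastic sparse transition matrix from
#'   [transition_matrix()].
#' @param f0 Initial density: a `dc_density` or a nonnegative numeric vector
#'   summing to 1.
#' @param alpha Restart damping in `[0, 1]`; weight of neighbour information
#'   versus the initial estimate. Default 0.9.
#' @param tol Absolute tolerance on the max-abs change per iteration
#'   (default 1e-9). Must be positive.
#' @param max_iter Iteration cap, default 1000.
#' @param check If `TRUE`, assert the unit-sum conservation law at every
#'   iteration (debugging aid).
#' @return A `dc_density` with `stage = "refined"`, `alpha`,
#'   `iterations_used` and `converged` recorded.
#' @export
refine_density <- function(P, f0, alpha = 0.9, tol = 1e-9, max_iter = 1000L,
                           check = FALSE) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1) {
    dc_abort_parameter("`alpha` must be a single value in [0, 1]")
  }
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    dc_abort_parameter("`tol` must be a positive number")
  }
  f0v <- dc_density_values(f0)
  if (nrow(P) != length(f0v)) {
    dc_abort_parameter("dimensions of `P` and `f0` disagree")
  }
  if (alpha == 0) {
    return(new_dc_density(f0v, "refined", alpha = 0, iterations_used = 0L,
                          converged = TRUE))
  }
  Pt <- Matrix::t(P)
  f <- f0v
  restart <- (1 - alpha) * f0v
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    fn <- as.numeric(alpha * (Pt %*% f) + restart)
    delta <- max(abs(fn - f))
    f <- fn
    if (check) {
      stopifnot(abs(sum(f) - 1) < 1e-9)
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "density refinement stopped at max_iter = %d without meeting tol (alpha = %g)",
      max_iter, alpha), class = "dc_convergence_warning")
  }
  new_dc_density(f, "refined", alpha = alpha, iterations_used = it,
                 converged = converged)
}

#' Tidy densities into a per-node tibble
#'
#' @param x A `dc_density`.
#' @param ... Unused.
#' @return A tibble with columns `node` and `density`.
#' @export
tidy.dc_density <- function(x, ...) {
  tibble(node = seq_along(x$values), density = x$values)
}
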