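# Seeded synthetic data generators.
#
# These emulate the structures the clustering method assumes: well-separated
# Gaussian mixtures on a grid (scaling and recovery experiments), a dense
# blob inside sparse uniform background (the classic toy that defeats
# variance-based model selection), non-convex crescents, and a graph-only
# input. Every generator routes all randomness through an explicit seed via
# withr, leaving the caller's RNG state untouched.

dc_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Gaussian mixture on a square grid
#'
#' `components` equal-weight isotropic Gaussians with standard deviation
#' `sigma`, centred on a `sqrt(components)` x `sqrt(components)` grid with
#' spacing `sep * sigma`. With the default `sep = 8` the components are
#' well separated; `sep = 3` is a useful hard variant.
#'
#' @param components Number of mixture components (a perfect square).
#' @param n Total number of points.
#' @param sep Centre spacing in units of `sigma`. Default 8.
#' @param sigma Component standard deviation. Default 1.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `x`, `y` and the generating component
#'   `label`.
#' @export
sim_gaussian_grid <- function(components = 64L, n = 4096L, sep = 8,
                              sigma = 1, seed = NULL) {
  g <- sqrt(components)
  if (g != round(g)) dc_abort_parameter("`components` must be a perfect square")
  g <- as.integer(g)
  centers <- expand.grid(cx = seq_len(g), cy = seq_len(g)) * sep * sigma
  dc_with_seed(seed, {
    lab <- sample.int(components, n, replace = TRUE)
    tibble(
      x = centers$cx[lab] + rnorm(n, sd = sigma),
      y = centers$cy[lab] + rnorm(n, sd = sigma),
      label = lab
    )
  })
}

#' Gaussian blobs on a line
#'
#' `clusters` equal-weight isotropic Gaussians with centres spaced
#' `sep * sigma` apart along the x axis. The `sep = 10` default gives the
#' canonical well-separated two-blob recovery case.
#'
#' @param n Total number of points.
#' @param clusters Number of blobs. Default 2.
#' @param sep Centre spacing in units of `sigma`. Default 10.
#' @param sigma Blob standard deviation. Default 1.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `x`, `y`, `label`.
#' @export
sim_blobs <- function(n = 400L, clusters = 2L, sep = 10, sigma = 1,
                      seed = NULL) {
  dc_with_seed(seed, {
    lab <- sample.int(clusters, n, replace = TRUE)
    tibble(
      x = (lab - 1) * sep * sigma + rnorm(n, sd = sigma),
      y = rnorm(n, sd = sigma),
      label = lab
    )
  })
}

#' Dense cluster inside sparse background
#'
#' A tight 2-D Gaussian (label 1) sitting inside sparse uniform noise on a
#' square (label 2). With the defaults the dataset has 240 points, matching
#' the classic toy used to illustrate density-mode clustering.
#'
#' @param n_cluster Points in the dense blob. Default 40.
#' @param n_background Uniform background points. Default 200.
#' @param sigma Blob standard deviation. Default 0.5.
#' @param half_width Background square is `[-half_width, half_width]^2`.
#'   Default 10.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `x`, `y`, `label`.
#' @export
sim_toy_background <- function(n_cluster = 40L, n_background = 200L,
                               sigma = 0.5, half_width = 10, seed = NULL) {
  dc_with_seed(seed, {
    tibble(
      x = c(rnorm(n_cluster, sd = sigma),
            runif(n_background, -half_width, half_width)),
      y = c(rnorm(n_cluster, sd = sigma),
            runif(n_background, -half_width, half_width)),
      label = rep(c(1L, 2L), c(n_cluster, n_background))
    )
  })
}

#' Two interleaved crescents
#'
#' The classic non-convex "two moons" shape pair with isotropic Gaussian
#' noise, for exercising arbitrary-shape cluster detection.
#'
#' @param n Total number of points (split evenly between the crescents).
#' @param noise Noise standard deviation. Default 0.05.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `x`, `y`, `label`.
#' @export
sim_crescents <- function(n = 300L, noise = 0.05, seed = NULL) {
  n1 <- n %/% 2L
  n2 <- n - n1
  dc_with_seed(seed, {
    t1 <- runif(n1, 0, pi)
    t2 <- runif(n2, 0, pi)
    tibble(
      x = c(cos(t1), 1 - cos(t2)) + rnorm(n, sd = noise),
      y = c(sin(t1), 0.5 - sin(t2)) + rnorm(n, sd = noise),
      label = rep(c(1L, 2L), c(n1, n2))
    )
  })
}

#' Graph-only input: Knn graph of two linked communities
#'
#' Two well-separated planar Gaussian communities are drawn and only their
#' exact Knn graph is returned, exercising the graph-only entry point (no
#' coordinates, uniform initial density, so the refined density is a
#' personalised-PageRank score). Each community has a genuine density mode,
#' the structure mode seeking assumes.
#'
#' @param n Number of nodes (split evenly across the two communities).
#' @param k Out-degree; default [default_k()]`(n)`.
#' @param gap Distance between the community centres in units of their unit
#'   standard deviation. Default 10.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `knn_graph` with an attribute `"truth"` giving the generating
#'   community of each node.
#' @export
sim_chain_graph <- function(n = 100L, k = NULL, gap = 10, seed = NULL) {
  n1 <- n %/% 2L
  n2 <- n - n1
  dc_with_seed(seed, {
    xy <- cbind(
      x = c(rnorm(n1, 0), rnorm(n2, gap)),
      y = c(rnorm(n1, 0), rnorm(n2, 0))
    )
    g <- knn_graph(xy, k = k %||% default_k(n))
    attr(g, "truth") <- rep(c(1L, 2L), c(n1, n2))
    g
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
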