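test_that("Knn density matches hand evaluation on 1-D {0, 1, 3}, K = 2", {
  g <- knn_graph(data.frame(x = c(0, 1, 3)), k = 2)
  # r_2 = (3, 2, 3); V_1 = 2; unnormalised (K-1)/(N V_1 r) = (1/18, 1/12, 1/18)
  raw <- knn_density(g, normalize = FALSE)
  expect_equal(raw$values, c(1 / 18, 1 / 12, 1 / 18), tolerance = 1e-12)
  # normalised: ratios 2:3:2
  f0 <- knn_density(g)
  expect_equal(f0$values, c(2, 3, 2) / 7, tolerance = 1e-12)
  expect_equal(sum(f0$values), 1, tolerance = 1e-12)
  expect_identical(f0$stage, "initial")
})

test_that("equal r_K implies equal densities (grid symmetry)", {
  # interior of a regular 1-D grid: every node's Kth neighbour distance equal
  g <- knn_graph(data.frame(x = seq(0, 10)), k = 2)
  f0 <- knn_density(g)$values
  interior <- 2:10
  expect_true(all(abs(f0[interior] - f0[interior][1]) < 1e-14))
})

test_that("high-dimensional evaluation survives in log space", {
  # 10 nodes whose r_K spans [0.5, 2], D = 1000: direct powers would
  # under/overflow by ~e600
  rk <- seq(0.5, 2, length.out = 10)
  edges <- data.frame(source = 1:10, target = c(2:10, 1), distance = rk)
  g <- as_knn_graph(edges)
  f0 <- knn_density(g, dim = 1000)$values
  # no NaN/Inf anywhere; values whose log-ratio to the maximum is within
  # double range are strictly positive (the rest underflow cleanly to 0 --
  # their true magnitude is ~1e-600)
  expect_true(all(is.finite(f0) & f0 >= 0))
  representable <- 1000 * (log(rk) - log(min(rk))) < 700
  expect_true(all(f0[representable] > 0))
  expect_true(all(diff(f0) <= 0)) # density ordering follows 1/r_K
  expect_equal(sum(f0), 1, tolerance = 1e-9)
  # high-precision oracle: f_i = rk_i^-D / sum_j rk_j^-D via python mpmath
  oracle <- tryCatch({
    out <- system2("python", c("-c", shQuote(paste0(
      "import mpmath as mp; mp.mp.dps = 300; ",
      "rk = [mp.mpf(str(v)) for v in [", paste(rk, collapse = ","), "]]; ",
      "w = [r**-1000 for r in rk]; s = sum(w); ",
      "print(' '.join(mp.nstr(x/s, 17) for x in w))"
    ))), stdout = TRUE, stderr = TRUE)
    as.numeric(strsplit(trimws(out[length(out)]), " ")[[1]])
  }, warning = function(w) NULL, error = function(e) NULL)
  if (!is.null(oracle) && length(oracle) == 10 && !anyNA(oracle)) {
    expect_equal(f0, oracle, tolerance = 1e-10)
  }
  # double-precision invariant that needs no oracle: log-ratios are exact
  expect_equal(log(f0[1] / f0[2]), -1000 * log(rk[1] / rk[2]),
               tolerance = 1e-9)
})

test_that("duplicate points get the highest finite density", {
  pts <- data.frame(x = c(0, 0, 0, 1, 2, 5), y = 0)
  g <- knn_graph(pts, k = 2)
  f0 <- knn_density(g)$values
  expect_true(all(is.finite(f0)))
  expect_true(all(f0[1:3] >= max(f0[4:6])))
  # all-identical points are degenerate
  g2 <- knn_graph(data.frame(x = c(1, 1, 1)), k = 2)
  expect_error(knn_density(g2), class = "dc_degenerate_error")
})

test_that("alpha = 0 returns the initial density unchanged", {
  g <- rand_graph(20, 3, seed = 1)
  f0 <- rand_density(20, seed = 2)
  P <- transition_matrix(g)
  out <- refine_density(P, f0, alpha = 0)
  expect_identical(out$values, f0)
  expect_identical(out$iterations_used, 0L)
})

test_that("uniform density is a fixed point on the complete graph", {
  g <- knn_graph(data.frame(x = rnorm(9), y = rnorm(9)), k = 8)
  P <- transition_matrix(g)
  f0 <- rep(1 / 9, 9)
  for (a in c(0.3, 0.9)) {
    out <- refine_density(P, f0, alpha = a)
    expect_equal(out$values, f0, tolerance = 1e-12)
  }
})

test_that("iteration matches the dense linear solve (closed form)", {
  # 3-node chain
  edges <- data.frame(source = c(1, 2, 3), target = c(2, 3, 2),
                      distance = 1)
  g <- as_knn_graph(edges)
  P <- transition_matrix(g)
  f0 <- c(0.5, 0.3, 0.2)
  out <- refine_density(P, f0, alpha = 0.9, tol = 1e-12, max_iter = 5000)
  exact <- solve(diag(3) - 0.9 * t(as.matrix(P)), 0.1 * f0)
  expect_equal(out$values, as.numeric(exact), tolerance = 1e-8)
  expect_equal(sum(out$values), 1, tolerance = 1e-9)
})

test_that("every iteration conserves the unit sum", {
  g <- rand_graph(40, 4, seed = 5)
  P <- transition_matrix(g)
  f0 <- rand_density(40, seed = 6)
  # check = TRUE asserts conservation internally at each step
  out <- refine_density(P, f0, alpha = 0.9, check = TRUE)
  expect_equal(sum(out$values), 1, tolerance = 1e-9)
  # explicit re-derivation of the first few iterates
  Pt <- Matrix::t(P)
  f <- f0
  for (t in 1:5) {
    f <- as.numeric(0.9 * (Pt %*% f) + 0.1 * f0)
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("residuals contract at least geometrically with rate alpha", {
  g <- rand_graph(60, 5, seed = 7)
  P <- transition_matrix(g)
  Pt <- Matrix::t(P)
  f0 <- rand_density(60, seed = 8)
  alpha <- 0.9
  f <- f0
  deltas <- numeric(30)
  for (t in 1:30) {
    fn <- as.numeric(alpha * (Pt %*% f) + (1 - alpha) * f0)
    deltas[t] <- max(abs(fn - f))
    f <- fn
  }
  bound <- deltas[1] * alpha^(0:29)
  expect_true(all(deltas <= bound + 1e-15))
})

test_that("alpha = 1 on an oscillating graph warns after max_iter", {
  edges <- data.frame(source = c(1, 2), target = c(2, 1), distance = 1)
  P <- transition_matrix(as_knn_graph(edges))
  expect_warning(
    out <- refine_density(P, c(1, 0), alpha = 1, max_iter = 50),
    class = "dc_convergence_warning"
  )
  expect_false(out$converged)
  expect_identical(out$iterations_used, 50L)
})

test_that("parameter validation for refinement", {
  g <- rand_graph(10, 2, seed = 3)
  P <- transition_matrix(g)
  f0 <- rep(0.1, 10)
  expect_error(refine_density(P, f0, alpha = 1.5),
               class = "dc_parameter_error")
  expect_error(refine_density(P, f0, tol = 0), class = "dc_parameter_error")
  expect_error(refine_density(P, f0, tol = -1), class = "dc_parameter_error")
})

test_that("alpha = 0.9 converges within 200 iterations on Gaussian data", {
  pts <- withr::with_seed(99, data.frame(x = rnorm(240), y = rnorm(240)))
  g <- knn_graph(pts) # default K = log2(240) = 8
  out <- refine_density(transition_matrix(g), knn_density(g), alpha = 0.9)
  expect_true(out$converged)
  expect_lt(out$iterations_used, 200)
})
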