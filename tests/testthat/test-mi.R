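test_that("integer digamma follows the harmonic-series identity", {
  expect_equal(digamma_int(1), -0.5772156649, tolerance = 1e-9)
  expect_equal(digamma_int(2), 0.4227843351, tolerance = 1e-9)
  # recurrence oracle psi(n+1) = psi(n) + 1/n
  for (n in 1:9) expect_equal(digamma_int(n + 1), digamma_int(n) + 1 / n)
  # base R digamma as an independent cross-check
  expect_equal(digamma_int(1:50), digamma(1:50), tolerance = 1e-12)
  expect_error(digamma_int(0), class = "afcn_invalid_argument")
})

test_that("KSG is near zero for independent pairs", {
  est <- vapply(1:20, function(s) {
    set.seed(s)
    ksg_mutual_information(runif(5000), runif(5000), ksg_params(seed = s))
  }, 0)
  expect_true(all(abs(est) < 0.05))
  expect_lt(abs(mean(est)), 0.01)
})

test_that("KSG matches the Gaussian closed form", {
  est <- vapply(1:20, function(s) {
    set.seed(s)
    z <- rbvn(10000, 0.9)
    ksg_mutual_information(z[, 1], z[, 2], ksg_params(seed = s))
  }, 0)
  expect_lt(abs(mean(est) - 0.8304), 0.02)
})

test_that("KSG error for Gaussian pairs shrinks with sample size", {
  err_at <- function(n) {
    mean(vapply(1:20, function(s) {
      set.seed(s)
      z <- rbvn(n, 0.6)
      abs(ksg_mutual_information(z[, 1], z[, 2], ksg_params(seed = s)) -
            (-0.5 * log(1 - 0.36)))
    }, 0))
  }
  errs <- vapply(c(500, 2000, 10000), err_at, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("KSG on a piecewise-uniform binned pair matches the plug-in MI", {
  set.seed(41)
  n <- 10000
  u <- rnorm(n)
  v <- 0.8 * u + 0.6 * rnorm(n)
  xb <- as.integer(cut(u, quantile(u, 0:4 / 4), include.lowest = TRUE))
  yb <- as.integer(cut(v, quantile(v, 0:4 / 4), include.lowest = TRUE))
  ksg <- ksg_mutual_information(xb + runif(n), yb + runif(n),
                                ksg_params(seed = 41))
  expect_lt(abs(ksg - plugin_mi(xb, yb)), 0.05)
})

test_that("KSG estimate is symmetric, deterministic, and unclipped", {
  set.seed(5)
  x <- rnorm(800)
  y <- rnorm(800)
  p <- ksg_params(seed = 3)
  expect_identical(ksg_mutual_information(x, y, p),
                   ksg_mutual_information(y, x, p))
  expect_identical(ksg_mutual_information(x, y, p),
                   ksg_mutual_information(x, y, p))
  # slightly negative estimates occur near independence and are kept
  est <- vapply(1:40, function(s) {
    set.seed(s + 100)
    ksg_mutual_information(rnorm(300), rnorm(300), ksg_params(seed = s))
  }, 0)
  expect_true(any(est < 0))
})

test_that("KSG input contracts are enforced", {
  p <- ksg_params()
  expect_error(ksg_mutual_information(rnorm(4), rnorm(4), p),
               class = "afcn_invalid_argument")      # N <= k
  expect_error(ksg_mutual_information(rnorm(10), rnorm(9), p),
               class = "afcn_invalid_argument")
  expect_error(ksg_mutual_information(c(rnorm(9), NA), rnorm(10), p),
               class = "afcn_invalid_argument")
  expect_warning(ksg_mutual_information(rep(1, 100), rnorm(100), p),
                 "constant")
  expect_error(ksg_params(k = 0), class = "afcn_invalid_argument")
})

test_that("all-to-all MI matrix is symmetric with zero diagonal", {
  set.seed(6)
  win <- matrix(rnorm(500 * 4), ncol = 4)
  m <- all_to_all_mi(win, ksg_params(seed = 2))
  expect_identical(m$values, t(m$values))
  expect_true(all(diag(m$values) == 0))
  expect_equal(m$n_channels, 4)
  # 2 channels: single mirrored pair
  m2 <- all_to_all_mi(win[, 1:2], ksg_params(seed = 2))
  expect_equal(sum(m2$values != 0), 2)
  expect_error(all_to_all_mi(win[, 1, drop = FALSE]),
               class = "afcn_invalid_argument")
})

test_that("a duplicated channel dominates its row of the MI matrix", {
  set.seed(7)
  base <- matrix(rnorm(1500 * 3), ncol = 3)
  win <- cbind(base, base[, 1])          # channel 4 duplicates channel 1
  m <- all_to_all_mi(win, ksg_params(seed = 7))$values
  expect_equal(unname(which.max(m[1, -1])), 3)   # pair (1,4) maximal in row 1
})

test_that("averaging MI matrices is the pointwise mean and reduces variance", {
  a <- fake_mi(matrix(c(0, 1, 1, 0), 2))
  b <- fake_mi(matrix(c(0, 3, 3, 0), 2))
  avg <- average_mi(list(a, b))
  expect_equal(avg$values[1, 2], 2)
  expect_identical(avg$window_index, "averaged")
  expect_identical(average_mi(list(a))$values, a$values)
  expect_error(average_mi(list()), class = "afcn_invalid_argument")

  # variance reduction across windows of a stationary coupled simulation
  lay <- generate_basket_layout(2, 2)
  adj <- matrix(0, 4, 4); adj[1, 2] <- adj[2, 1] <- 1
  truth <- structure(list(n_nodes = 4L, adjacency = adj, coupling = adj * 0.6,
                          model = "manual", seed = 1L),
                     class = "planted_network")
  spread <- vapply(1:5, function(s) {
    rec <- simulate_coupled_af(lay, truth, sim_config(duration_s = 10, seed = s))
    ws <- segment_windows(rec, window_s = 2, n_windows = 5)
    mi <- windowed_mi(ws, ksg_params(seed = s))
    off <- function(m) m$values[upper.tri(m$values)]
    c(avg = var(off(mi$averaged)),
      single = mean(vapply(mi$per_window, function(m) var(off(m)), 0)))
  }, c(avg = 0, single = 0))
  expect_lt(mean(spread["avg", ]), mean(spread["single", ]))
})

test_that("windowed MI is deterministic under a fixed seed", {
  lay <- generate_basket_layout(2, 2)
  truth <- generate_planted_network(4, "random", m = 3, seed = 2)
  rec <- simulate_coupled_af(lay, truth, sim_config(duration_s = 10, seed = 8))
  ws <- segment_windows(rec, window_s = 2, n_windows = 5)
  m1 <- windowed_mi(ws, ksg_params(seed = 1))
  m2 <- windowed_mi(ws, ksg_params(seed = 1))
  expect_identical(m1$averaged$values, m2$averaged$values)
})
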