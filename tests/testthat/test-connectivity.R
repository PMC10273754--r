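test_that("zero-lag correlation is the ordinary symmetric Pearson matrix", {
  ts <- simulate_var_timeseries(6, 80, seed = 10)
  C0 <- delayed_correlation(ts, 0)
  expect_equal(unclass(C0), stats::cor(t(ts)), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(diag(C0), rep(1, 6), ignore_attr = TRUE)
  expect_equal(unclass(C0), t(unclass(C0)), ignore_attr = TRUE)
})

test_that("a perfect lagged copy correlates to one at its delay", {
  x <- stats::rnorm(60)
  ts <- rbind(x, c(rep(0, 3), x[1:57]))  # region 2 lags region 1 by 3
  C3 <- delayed_correlation(ts, 3)
  expect_equal(C3[1, 2], 1, tolerance = 1e-10)
})

test_that("the printed two-region worked example matches hand computation", {
  ts <- rbind(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
  C1 <- delayed_correlation(ts, 1)
  expect_equal(C1[1, 2], stats::cor(c(1, 2, 3, 4), c(1, 4, 3, 6)))
  expect_equal(C1[2, 1], stats::cor(c(2, 1, 4, 3), c(2, 3, 4, 5)))
})

test_that("delay preconditions and flat regions are handled", {
  ts <- simulate_var_timeseries(3, 20, seed = 1)
  expect_error(delayed_correlation(ts, 18), "too large")
  ts[2, ] <- 7
  expect_warning(C1 <- delayed_correlation(ts, 1), "zero-variance")
  expect_true(all(C1[2, -2] == 0) && all(C1[-2, 2] == 0))
})

test_that("the symmetric/anti-symmetric split is exact and unique", {
  C <- matrix(c(1, 0.5, 0.1, 1), 2, byrow = TRUE)
  d <- antisymmetric_decomposition(C)
  expect_equal(d$S, matrix(c(1, 0.3, 0.3, 1), 2), ignore_attr = TRUE)
  expect_equal(d$K, matrix(c(0, 0.2, -0.2, 0), 2, byrow = TRUE),
               ignore_attr = TRUE)
  withr::with_seed(42, {
    for (i in 1:5) {
      M <- matrix(stats::rnorm(36), 6, 6)
      dd <- antisymmetric_decomposition(M)
      expect_lt(max(abs(dd$S + dd$K - M)), 1e-12)
      expect_equal(dd$S, t(dd$S), tolerance = 1e-14, ignore_attr = TRUE)
      expect_equal(dd$K, -t(dd$K), tolerance = 1e-14, ignore_attr = TRUE)
      expect_equal(diag(dd$K), rep(0, 6), ignore_attr = TRUE)
    }
  })
  sym <- crossprod(matrix(stats::rnorm(16), 4))
  expect_equal(max(abs(antisymmetric_decomposition(sym)$K)), 0,
               tolerance = 1e-14)
  expect_error(antisymmetric_decomposition(matrix(1, 2, 3)), "square")
})

test_that("the anti-symmetric part vanishes at delay zero", {
  for (seed in 1:5) {
    ts <- simulate_var_timeseries(8, 60, seed = seed)
    K0 <- antisymmetric_decomposition(delayed_correlation(ts, 0))$K
    expect_lt(max(abs(K0)), 1e-12)
  }
})

test_that("swapping leader and follower transposes the delayed matrix", {
  ts <- simulate_var_timeseries(5, 70, seed = 21)
  d <- 2
  C <- delayed_correlation(ts, d)
  T_ <- ncol(ts)
  # follower-indexed matrix: rows are the later (shifted) series
  swapped <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    swapped[i, j] <- stats::cor(ts[i, (1 + d):T_], ts[j, 1:(T_ - d)])
  }
  expect_equal(unclass(C), t(swapped), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("directed networks zero the negatives and keep one direction per pair", {
  K <- matrix(c(0, 0.2, -0.2, 0), 2, byrow = TRUE)
  W <- build_directed_network(K, 1)
  expect_equal(unclass(W), matrix(c(0, 0.2, 0, 0), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(unclass(build_directed_network(matrix(0, 3, 3), 1)),
               matrix(0, 3, 3), ignore_attr = TRUE)
  withr::with_seed(9, {
    M <- matrix(stats::rnorm(49), 7)
    K <- (M - t(M)) / 2
    W <- build_directed_network(K, 1)
    expect_equal(unclass(W) - t(unclass(W)), K, ignore_attr = TRUE,
                 tolerance = 1e-14)
    expect_true(all(unclass(W)[t(unclass(W)) > 0] == 0))
  })
  expect_error(build_directed_network(matrix(c(0, 1, 1, 0), 2), 1),
               "not anti-symmetric")
})

test_that("group averaging is the element-wise mean", {
  W1 <- matrix(0, 3, 3); W1[1, 2] <- 0.4
  W2 <- matrix(0, 3, 3); W2[2, 1] <- 0.2
  attr(W1, "delay") <- attr(W2, "delay") <- 1L
  avg <- group_average_network(list(W1, W2))
  expect_equal(avg[1, 2], 0.2)
  expect_equal(avg[2, 1], 0.1)
  same <- group_average_network(list(W1, W1, W1))
  expect_equal(unclass(same), unclass(W1), ignore_attr = TRUE)
  expect_error(group_average_network(list()), "empty")
  expect_error(group_average_network(list(W1, matrix(0, 2, 2))), "shape")
})

test_that("weight histograms bin the nonzero off-diagonal entries", {
  M <- matrix(0, 2, 2)
  M[1, 2] <- 0.1; M[2, 1] <- 0.1
  M3 <- matrix(0, 3, 3)
  M3[1, 2] <- 0.1; M3[2, 1] <- 0.1; M3[1, 3] <- 0.3
  h <- weight_histogram(M3, 2)
  expect_equal(h$count, c(2L, 1L))
  expect_equal(sum(h$count), 3L)
  empty <- weight_histogram(matrix(0, 4, 4), 3)
  expect_equal(nrow(empty), 0L)
  withr::with_seed(2, {
    W <- random_weighted_network(8, seed = 2)
    h <- weight_histogram(W, 5)
    expect_equal(sum(h$count), sum(unclass(W) > 0))
  })
})

test_that("weight distributions narrow as the temporal delay grows", {
  # tendency over seeds: positive-weight IQR of the group-average network
  # trends downward from delay 1 to 5 for autocorrelated lagged signals
  # conditions: dense lag-1 backbone with heterogeneous strengths, so the
  # structural weights (broad at delay 1, attenuated by the signal
  # autocorrelation at higher delays) dominate the positive-weight quartiles
  down <- 0
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    cp <- hub_ring_couplings(12, ring_prob = 0.3, edges_per_lag = 36,
                             lags = 1L, strength = c(0.1, 0.45),
                             sign_mix = TRUE, seed = seed)
    nets <- lapply(1:5, function(d) {
      ws <- lapply(1:5, function(s) {
        ts <- simulate_var_timeseries(12, 150, cp, seed = 100 * seed + s,
                                      ar1 = 0.3)
        build_directed_network(
          antisymmetric_decomposition(delayed_correlation(ts, d))$K, d)
      })
      group_average_network(ws)
    })
    iqrs <- vapply(nets, function(W) {
      v <- W[row(W) != col(W)]
      stats::IQR(v[v > 0])
    }, numeric(1))
    slope <- stats::coef(stats::lm(iqrs ~ seq_along(iqrs)))[2]
    down <- down + (slope < 0)
  }
  expect_gt(down, n_seeds / 2)
})

test_that("with no couplings the anti-symmetric weights are centred on zero", {
  means <- vapply(1:50, function(s) {
    ts <- simulate_var_timeseries(10, 100, seed = 1000 + s)
    K <- antisymmetric_decomposition(delayed_correlation(ts, 1))$K
    mean(K[row(K) != col(K)])
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-12)
})

test_that("network matrices round-trip through TSV with their sidecar", {
  W <- random_weighted_network(6, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(W, path, delay = 2, tr_seconds = 3)
  back <- read_network(path)
  expect_equal(unclass(back), unclass(W), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(attr(back, "delay"), 2)
})
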