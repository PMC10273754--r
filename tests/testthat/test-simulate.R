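test_that("coupling tables are validated and stability is assessed", {
  expect_error(couplings(1, 1, 1, 0.5), "self-couplings")
  expect_error(couplings(1, 2, 0, 0.5), "lags must be >= 1")
  # a one-way coupling never feeds back: stable at any strength
  expect_equal(coupling_spectral_radius(couplings(1, 2, 1, 5), 2), 0)
  # a mutual strength-1.2 loop is self-reinforcing and must be rejected
  loop <- couplings(c(1, 2), c(2, 1), c(1, 1), c(1.2, 1.2))
  expect_gte(coupling_spectral_radius(loop, 2), 1)
  expect_error(simulate_var_timeseries(2, 100, loop),
               "spectral radius")
})

test_that("the null process is i.i.d. noise and bit-reproducible", {
  ts1 <- simulate_var_timeseries(5, 300, noise_sd = 1, seed = 7)
  ts2 <- simulate_var_timeseries(5, 300, noise_sd = 1, seed = 7)
  expect_identical(ts1, ts2)
  expect_equal(dim(ts1), c(5L, 300L))
  ts3 <- simulate_var_timeseries(5, 300, noise_sd = 1, seed = 8)
  expect_false(identical(unclass(ts1), unclass(ts3)))
  # marginal sd near 1 for the pure-noise process
  expect_lt(abs(stats::sd(as.vector(ts1)) - 1), 0.05)
})

test_that("a lagged coupling raises the delayed correlation at its lag", {
  cp <- couplings(1, 2, 2, 0.9)
  ts <- simulate_var_timeseries(2, 500, cp, noise_sd = 0.1, seed = 3)
  # oracle: the lagged-correlation definition applied directly
  T_ <- ncol(ts)
  r_lag2 <- stats::cor(ts[1, 1:(T_ - 2)], ts[2, 3:T_])
  r_lag0 <- stats::cor(ts[1, ], ts[2, ])
  expect_gt(r_lag2, r_lag0)
  expect_gt(r_lag2, 0.5)
  expect_error(simulate_var_timeseries(2, 2, cp), "below n_timepoints")
})

test_that("group classification follows the strict 1.11 amyloid cut-off", {
  expect_equal(as.character(classify_group("CN", 1.0)), "CN_Abeta_neg")
  expect_equal(as.character(classify_group("MCI", 1.05)), "excluded")
  expect_equal(as.character(classify_group("CN", 1.11)), "CN_Abeta_neg")
  expect_equal(as.character(classify_group("CN", 1.12)), "CN_Abeta_pos")
  expect_equal(as.character(classify_group("AD", 1.4)), "AD_Abeta_pos")
  expect_equal(as.character(classify_group("AD", 1.11)), "excluded")
  expect_error(classify_group("SMC", 1.2), "unknown diagnosis")
  expect_error(classify_group("CN", -1), "positive")
})

test_that("simulated cohorts honour the designed group sizes exactly", {
  des <- default_cohort_design(seed = 2, n_regions = 20)
  coh <- simulate_cohort(des$groups, 20, 60, seed = 2,
                         jitter_sd = 0.1, ar1 = 0.3)
  counts <- table(coh$subjects$group)
  expect_equal(unname(counts[c("CN_Abeta_neg", "CN_Abeta_pos",
                               "MCI_Abeta_pos", "AD_Abeta_pos")]),
               c(81L, 36L, 31L, 18L), ignore_attr = TRUE)
  expect_equal(nrow(coh$subjects), 166L)
  expect_length(coh$timeseries, 166L)
  expect_true(all(vapply(coh$timeseries, nrow, 0L) == 20L))
  # stored labels always consistent with the classifier
  expect_identical(
    as.character(classify_group(coh$subjects$diagnosis,
                                coh$subjects$global_abeta_suvr)),
    coh$subjects$group)
})

test_that("cohorts are deterministic in the seed but vary across seeds", {
  c1 <- tiny_cohort(seed = 5, n_per_group = c(3, 2, 2, 2))
  c2 <- tiny_cohort(seed = 5, n_per_group = c(3, 2, 2, 2))
  c3 <- tiny_cohort(seed = 6, n_per_group = c(3, 2, 2, 2))
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$timeseries, c2$timeseries)
  expect_false(identical(c1$timeseries[[1]], c3$timeseries[[1]]))
  expect_identical(table(c1$subjects$group), table(c3$subjects$group))
})

test_that("quadratic outcomes are attached by exact arithmetic", {
  coh <- tiny_cohort(seed = 3, n_per_group = c(2, 1, 1, 1))
  ids <- coh$subjects$subject_id
  m <- stats::setNames(rep(2, length(ids)), ids)
  coh2 <- attach_quadratic_outcome(coh, m, quadratic_link(0, 0, 1), "y2")
  expect_equal(coh2$subjects$y2, rep(4, length(ids)))
  m3 <- stats::setNames(rep(3, length(ids)), ids)
  coh3 <- attach_quadratic_outcome(coh, m3, quadratic_link(1, -2, 0), "y3")
  expect_equal(coh3$subjects$y3, rep(-5, length(ids)))
  expect_error(
    attach_quadratic_outcome(coh, m[-1], quadratic_link(), "y"),
    "missing measure values")
})

test_that("cohorts round-trip through TSV/CSV exactly", {
  coh <- tiny_cohort(seed = 4, n_per_group = c(1, 1, 1, 1))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  expect_equal(nrow(manifest), nrow(coh$subjects) + 1L)
  expect_true(all(file.exists(manifest$file)))
  back <- read_cohort(dir)
  expect_equal(back$subjects, coh$subjects, ignore_attr = TRUE)
  for (id in coh$subjects$subject_id) {
    expect_equal(unclass(back$timeseries[[id]]),
                 unclass(coh$timeseries[[id]]), ignore_attr = TRUE)
  }
  blocker <- file.path(dir, "blocked")
  file.create(blocker)
  expect_error(write_cohort(coh, file.path(blocker, "sub")), "blocked")
})
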