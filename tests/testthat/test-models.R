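test_that("noiseless quadratic data are interpolated exactly", {
  d <- data.frame(m = seq(-2, 2, length.out = 30))
  d$y <- 2 + 3 * d$m - d$m^2
  fit <- fit_quadratic_model(d, "y", measures = "m", iqr_k = NULL)
  est <- tidy(fit)$estimate
  expect_equal(est, c(2, 3, -1), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(glance(fit)$r_squared_adj, 1, tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(m = seq_len(20), y = 5)
  expect_error(fit_quadratic_model(d, "y", "m", iqr_k = NULL),
               "zero variance")
  d2 <- data.frame(m = stats::rnorm(20))
  d2$m_dup <- d2$m
  d2$y <- d2$m + stats::rnorm(20)
  expect_error(
    fit_quadratic_model(d2, "y", measures = c("m", "m_dup"),
                        include_square = FALSE, iqr_k = NULL),
    "aliased|rank")
  expect_error(fit_quadratic_model(d2, "y", "missing_col"), "not in data")
})

test_that("categorical covariates expand with the stated reference level", {
  withr::with_seed(10, {
    d <- data.frame(m = stats::rnorm(60),
                    diagnosis = sample(c("CN", "MCI", "AD"), 60, TRUE),
                    sex = sample(c("M", "F"), 60, TRUE))
    d$y <- d$m + (d$diagnosis == "AD") * 2 + stats::rnorm(60)
  })
  fit <- fit_quadratic_model(d, "y", "m", covariates = c("diagnosis", "sex"),
                             iqr_k = NULL)
  terms <- tidy(fit)$term
  expect_true(all(c("diagnosisMCI", "diagnosisAD", "sexM") %in% terms))
  expect_false(any(grepl("diagnosisCN|sexF", terms)))
})

test_that("the outlier screen is applied to the dependent variable", {
  withr::with_seed(11, {
    d <- data.frame(m = stats::rnorm(50))
    d$y <- 1 + 2 * d$m + stats::rnorm(50, sd = 0.2)
    d$y[1] <- 50
  })
  fit <- fit_quadratic_model(d, "y", "m", include_square = FALSE)
  expect_equal(fit$excluded_outliers, 1L)
  expect_equal(fit$n_used, 49L)
  expect_equal(tidy(fit)$estimate[2], 2, tolerance = 0.1)
})

test_that("model statistics agree with their definitional formulas", {
  withr::with_seed(12, {
    d <- data.frame(m = stats::rnorm(80), a = stats::rnorm(80))
    d$y <- 1 + d$m - 0.5 * d$m^2 + 0.3 * d$a + stats::rnorm(80)
  })
  fit <- fit_quadratic_model(d, "y", "m", covariates = "a", iqr_k = NULL)
  lmfit <- stats::lm(y ~ m + I(m^2) + a, data = d)
  expect_equal(tidy(fit)$estimate, unname(stats::coef(lmfit)),
               tolerance = 1e-10)
  rss <- sum(stats::residuals(lmfit)^2)
  n <- nrow(d); k <- 4
  expect_equal(glance(fit)$aic, n * log(rss / n) + 2 * k, tolerance = 1e-10)
  # normal equations hold at the solution
  X <- stats::model.matrix(lmfit)
  expect_lt(max(abs(t(X) %*% stats::residuals(lmfit))), 1e-8)
})

test_that("quadratic coefficients are recovered through the generator link", {
  hits <- 0
  n_rep <- 10
  for (seed in seq_len(n_rep)) {
    coh <- tiny_cohort(seed = seed, n_regions = 6, n_timepoints = 30,
                       n_per_group = c(40, 40, 40, 30))
    ids <- coh$subjects$subject_id
    mv <- withr::with_seed(seed, stats::setNames(stats::runif(length(ids), -2, 2), ids))
    coh <- attach_quadratic_outcome(
      coh, mv, quadratic_link(1, 0.5, -1, noise_sd = 0.5), "y",
      seed = seed + 500)
    df <- coh$subjects
    df$m <- unname(mv[df$subject_id])
    fit <- fit_quadratic_model(df, "y", "m", iqr_k = NULL)
    co <- tidy(fit)
    i <- match("I(m^2)", co$term)
    ci <- co$estimate[i] + c(-1.96, 1.96) * co$std_error[i]
    hits <- hits + (ci[1] <= -1 && -1 <= ci[2])
  }
  expect_gte(hits, n_rep - 2)
})

test_that("AIC selection honours the hierarchy rule and tie ordering", {
  sets <- asymnet:::admissible_term_sets(c("a", "b"))
  expect_length(sets, 9L)
  sizes <- vapply(sets, function(s) length(s$lin) + length(s$sq), 0)
  expect_true(all(diff(sizes) >= 0))
  # squares never appear without their linear term
  for (s in sets) expect_true(all(s$sq %in% s$lin))
})

test_that("with no candidate measures the selection equals the plain fit", {
  withr::with_seed(13, {
    d <- data.frame(a = stats::rnorm(40))
    d$y <- 2 + d$a + stats::rnorm(40)
  })
  sel <- aic_select(d, "y", measures = character(), covariates = "a",
                    iqr_k = NULL)
  fit <- fit_quadratic_model(d, "y", measures = character(),
                             covariates = "a", include_square = FALSE,
                             iqr_k = NULL)
  expect_equal(sel$best$aic, fit$aic)
  expect_equal(tidy(sel$best), tidy(fit))
  expect_length(sel$selected_terms, 0L)
})

test_that("strong quadratic signal in one measure is selected, noise is not", {
  # AIC admits a spurious term with small probability per draw, so both
  # checks are Monte-Carlo tendencies rather than single-draw assertions
  exact <- 0; contains <- 0; null_empty <- 0
  n_rep <- 15
  for (seed in seq_len(n_rep)) {
    d <- withr::with_seed(300 + seed, {
      d <- data.frame(GE = stats::rnorm(200), CC = stats::rnorm(200))
      d$y <- d$GE + d$GE^2 + stats::rnorm(200, sd = 0.3)
      d$z <- stats::rnorm(200)
      d
    })
    sel <- aic_select(d, "y", measures = c("CC", "GE"), iqr_k = NULL)
    exact <- exact + setequal(sel$selected_terms, c("GE", "I(GE^2)"))
    contains <- contains + all(c("GE", "I(GE^2)") %in% sel$selected_terms)
    sel0 <- aic_select(d, "z", measures = c("CC", "GE"), iqr_k = NULL)
    null_empty <- null_empty + (length(sel0$selected_terms) == 0L)
  }
  expect_equal(contains, n_rep)
  expect_gte(exact, n_rep - 3)
  expect_gt(null_empty, n_rep / 2)
})

test_that("association tables cover every outcome and delay with FDR", {
  coh <- tiny_cohort(seed = 16, n_regions = 12, n_timepoints = 80,
                     n_per_group = c(6, 8, 8, 8))
  auc <- cohort_auc_table(coh, delays = 1:2, step = 0.1)
  res <- associate_network_measures(
    coh, auc, outcomes = c("ADAS13", "mPACC"))
  expect_equal(nrow(res$table), 2 * 2)
  expect_true(all(res$table$n_used + res$table$excluded_outliers <= 24))
  expect_true(all(res$table$model_p_fdr >= res$table$model_p - 1e-12))
  expect_s3_class(glance(res$fits[["ADAS13@1"]]), "tbl_df")
})
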