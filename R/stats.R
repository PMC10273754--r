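#' Two-sample permutation test on the difference of means
#'
#' Tests the null of exchangeability between two groups using the difference
#' of group means as the statistic. Group labels are permuted uniformly; the
#' two-tailed Monte-Carlo p-value uses the add-one correction
#' `p = (1 + #\{|T_perm| >= |T_obs|\}) / (1 + n_permutations)`, so it is never
#' below `1 / (n_permutations + 1)`. When the number of distinct label splits
#' is at most `n_permutations` (or `exact = TRUE`), all splits are enumerated
#' and the exact p-value `#\{|T| >= |T_obs|\} / n_splits` is returned instead.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @param n_permutations Number of random permutations (default 10000).
#' @param seed Optional seed for the permutation draws.
#' @param exact Force (or forbid) exhaustive enumeration; `NULL` chooses
#'   automatically.
#' @return An object of class `asy_perm_test`; see [tidy.asy_perm_test()].
#' @examples
#' pt <- permutation_test(c(10, 11, 12), c(0, 1, 2), n_permutations = 1000)
#' pt$p_value  # exact: 2/20
#' @export
permutation_test <- function(values_a, values_b, n_permutations = 10000,
                             seed = NULL, exact = NULL) {
  abort_if(length(values_a) < 2 || length(values_b) < 2,
           "each group needs at least 2 values")
  abort_if(n_permutations < 1, "n_permutations must be >= 1")
  na <- length(values_a)
  pooled <- c(values_a, values_b)
  n <- length(pooled)
  observed <- mean(values_a) - mean(values_b)
  n_splits <- choose(n, na)
  if (is.null(exact)) exact <- n_splits <= n_permutations
  tol <- 1e-12 * max(1, abs(observed))
  if (exact) {
    splits <- utils::combn(n, na)
    tot <- sum(pooled)
    stats_perm <- apply(splits, 2, function(ix) {
      sa <- sum(pooled[ix])
      sa / na - (tot - sa) / (n - na)
    })
    p <- mean(abs(stats_perm) >= abs(observed) - tol)
    n_used <- n_splits
  } else {
    stats_perm <- maybe_with_seed(seed, vapply(seq_len(n_permutations),
      function(i) {
        ix <- sample.int(n, na)
        mean(pooled[ix]) - mean(pooled[-ix])
      }, numeric(1)))
    p <- (1 + sum(abs(stats_perm) >= abs(observed) - tol)) /
      (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(observed_diff = observed, p_value = p,
                 n_permutations = n_used, exact = exact,
                 n_a = na, n_b = n - na, seed = seed),
            class = "asy_perm_test")
}

#' @export
print.asy_perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (difference of means, %s)\n",
              if (x$exact) "exact enumeration" else "Monte Carlo"))
  cat(sprintf("  observed diff = %.4g, p = %.4g (%d %s)\n",
              x$observed_diff, x$p_value, x$n_permutations,
              if (x$exact) "splits" else "permutations"))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure over a family of p-values: adjusted p-values are
#' monotone and at most 1, and a hypothesis is rejected exactly when its
#' adjusted p-value is at most `q`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q Target false discovery rate in `(0, 1)`.
#' @return A tibble with columns `p_value`, `p_adjusted`, `rejected`, in the
#'   input order.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  abort_if(anyNA(p_values) || any(p_values < 0 | p_values > 1),
           "p-values must lie in [0, 1]")
  abort_if(q <= 0 || q >= 1, "q must be in (0, 1)")
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, p_adjusted = adj, rejected = adj <= q)
}

#' Interquartile-range outlier screen
#'
#' Flags values inside the Tukey fences `[Q1 - k * IQR, Q3 + k * IQR]`, with
#' quartiles computed by linear interpolation between order statistics
#' (`stats::quantile` type 7). Applied to a model's dependent variable before
#' fitting so that single extreme scores do not dominate the regression.
#'
#' @param values Numeric vector; `NA`s propagate as `NA` flags.
#' @param k Fence multiplier (default 1.5).
#' @return Logical inclusion flags. With fewer than 4 non-missing values all
#'   are included, with a warning.
#' @export
iqr_filter <- function(values, k = 1.5) {
  ok <- !is.na(values)
  if (sum(ok) < 4) {
    warning("fewer than 4 values; all included")
    return(ifelse(ok, TRUE, NA))
  }
  qs <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  lo <- qs[1] - k * iqr
  hi <- qs[2] + k * iqr
  ifelse(ok, values >= lo & values <= hi, NA)
}

#' Permutation comparison of all group pairs
#'
#' Runs [permutation_test()] on the AUC values of every group pair, for every
#' measure and delay present in the table, then applies Benjamini-Hochberg
#' correction across the whole family of contrasts x measures x delays.
#'
#' @param auc_table Long table with columns `subject_id`, `group`, `measure`,
#'   `delay`, `auc` (see [cohort_auc_table()]).
#' @param n_permutations Permutations per test.
#' @param seed Seed for all permutation draws.
#' @param q FDR level.
#' @return A tibble of class `asy_comparison` with one row per contrast x
#'   measure x delay: `group_a`, `group_b`, `measure`, `delay`,
#'   `observed_diff` (mean_a - mean_b), `p_raw`, `p_fdr`, `significant`.
#' @export
compare_all_groups <- function(auc_table, n_permutations = 10000,
                               seed = NULL, q = 0.05) {
  need <- c("subject_id", "group", "measure", "delay", "auc")
  abort_if(!all(need %in% names(auc_table)),
           "auc_table must have columns %s", paste(need, collapse = ", "))
  groups <- intersect(group_levels(), unique(as.character(auc_table$group)))
  if (length(groups) == 0) groups <- sort(unique(as.character(auc_table$group)))
  abort_if(length(groups) < 2, "need at least 2 groups")
  pairs <- utils::combn(groups, 2)
  grid <- tidyr::expand_grid(
    pair = seq_len(ncol(pairs)),
    measure = unique(auc_table$measure),
    delay = sort(unique(auc_table$delay)))
  rows <- maybe_with_seed(seed, purrr::pmap(grid, function(pair, measure, delay) {
    ga <- pairs[1, pair]
    gb <- pairs[2, pair]
    va <- auc_table$auc[auc_table$group == ga & auc_table$measure == measure &
                          auc_table$delay == delay]
    vb <- auc_table$auc[auc_table$group == gb & auc_table$measure == measure &
                          auc_table$delay == delay]
    pt <- permutation_test(va, vb, n_permutations = n_permutations)
    tibble::tibble(group_a = ga, group_b = gb, measure = measure,
                   delay = delay, observed_diff = pt$observed_diff,
                   p_raw = pt$p_value)
  }))
  out <- dplyr::bind_rows(rows)
  corr <- fdr_bh(out$p_raw, q = q)
  out$p_fdr <- corr$p_adjusted
  out$significant <- corr$rejected
  class(out) <- c("asy_comparison", class(out))
  attr(out, "q") <- q
  attr(out, "n_permutations") <- n_permutations
  out
}
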