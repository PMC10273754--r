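#' Tidy a permutation test result
#'
#' @param x An `asy_perm_test`.
#' @param ... Unused.
#' @return A one-row tibble with the observed mean difference, p-value,
#'   number of permutations (or enumerated splits) and group sizes.
#' @export
tidy.asy_perm_test <- function(x, ...) {
  tibble::tibble(observed_diff = x$observed_diff, p_value = x$p_value,
                 n_permutations = x$n_permutations, exact = x$exact,
                 n_a = x$n_a, n_b = x$n_b)
}

#' Tidy and glance methods for quadratic association models
#'
#' `tidy()` returns the per-coefficient table (estimate, standard error,
#' t-statistic, p-value); `glance()` the one-row model summary (F-test,
#' adjusted R-squared, AIC, sample bookkeeping).
#'
#' @param x An `asy_model_fit`.
#' @param ... Unused.
#' @export
tidy.asy_model_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.asy_model_fit
#' @export
glance.asy_model_fit <- function(x, ...) {
  tibble::tibble(r_squared_adj = x$r_squared_adj,
                 f_statistic = x$f_statistic,
                 model_p_value = x$model_p_value, aic = x$aic,
                 n_used = x$n_used, excluded_outliers = x$excluded_outliers,
                 n_missing = x$n_missing)
}

#' Tidy an AIC model selection
#'
#' @param x An `asy_model_selection`.
#' @param ... Unused.
#' @return The candidate table (term set, number of terms, AIC) with a
#'   `selected` flag.
#' @export
tidy.asy_model_selection <- function(x, ...) {
  out <- x$candidates
  sel <- if (length(x$selected_terms))
    paste(x$selected_terms, collapse = " + ") else "(covariates only)"
  out$selected <- out$terms == sel & out$aic == min(out$aic)
  out
}

#' @rdname tidy.asy_model_selection
#' @export
glance.asy_model_selection <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(outcome = x$outcome,
                   selected_terms = if (length(x$selected_terms))
                     paste(x$selected_terms, collapse = " + ")
                   else "(covariates only)"),
    glance(x$best))
}
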