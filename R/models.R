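#' Quadratic association model between an outcome and network measures
#'
#' Ordinary least squares of an outcome (pathology SUVR or cognitive score)
#' on network-measure AUC terms — each measure optionally accompanied by its
#' square, capturing nonlinear trajectories along the disease continuum —
#' plus demographic covariates. The dependent variable is screened with the
#' 1.5-interquartile-range rule before fitting ([iqr_filter()]); character
#' covariates become factors with a stated reference level (diagnosis: CN).
#'
#' @param data Data frame with one row per subject.
#' @param outcome Name of the dependent-variable column.
#' @param measures Character vector of measure columns entering linearly.
#' @param covariates Character vector of covariate columns (always included).
#' @param include_square `TRUE` to add the square of every measure term,
#'   `FALSE` for linear terms only, or a character vector naming the subset
#'   of measures whose squares enter.
#' @param iqr_k Fence multiplier for the outlier screen on the outcome;
#'   `NULL` disables the screen.
#' @param ref_levels Named list of reference levels for categorical
#'   covariates.
#' @return An object of class `asy_model_fit` carrying the `lm` fit,
#'   per-coefficient tests, overall F-test, adjusted R-squared, AIC
#'   (`n * log(RSS / n) + 2k`, `k` mean parameters including the intercept),
#'   variance-inflation diagnostics, and the n used / excluded / missing
#'   bookkeeping. See [tidy.asy_model_fit()] and [glance.asy_model_fit()].
#' @examples
#' d <- data.frame(m = seq(-2, 2, length.out = 30))
#' d$y <- 2 + 3 * d$m - d$m^2
#' fit <- fit_quadratic_model(d, "y", measures = "m", iqr_k = NULL)
#' glance(fit)$r_squared_adj
#' @export
fit_quadratic_model <- function(data, outcome, measures,
                                covariates = character(),
                                include_square = TRUE, iqr_k = 1.5,
                                ref_levels = list(diagnosis = "CN",
                                                  sex = "F")) {
  cols <- c(outcome, measures, covariates)
  missing_cols <- setdiff(cols, names(data))
  abort_if(length(missing_cols) > 0, "columns not in data: %s",
           paste(missing_cols, collapse = ", "))
  df <- tibble::as_tibble(data[, cols, drop = FALSE])
  n_total <- nrow(df)
  complete <- stats::complete.cases(df)
  n_missing <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  excluded <- 0L
  if (!is.null(iqr_k)) {
    keep <- suppressWarnings(iqr_filter(df[[outcome]], k = iqr_k))
    excluded <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  for (cv in covariates) {
    if (is.character(df[[cv]]) || is.factor(df[[cv]])) {
      df[[cv]] <- factor(df[[cv]])
      ref <- ref_levels[[cv]]
      if (!is.null(ref) && ref %in% levels(df[[cv]])) {
        df[[cv]] <- stats::relevel(df[[cv]], ref = ref)
      }
    }
  }
  abort_if(stats::var(df[[outcome]]) == 0,
           "outcome '%s' has zero variance", outcome)
  squares <- if (is.character(include_square)) include_square
             else if (isTRUE(include_square)) measures
             else character()
  terms <- c(measures,
             if (length(squares)) sprintf("I(%s^2)", squares),
             covariates)
  fml <- stats::reformulate(c("1", terms), response = sprintf("`%s`", outcome))
  X <- stats::model.matrix(fml, data = df)
  abort_if(nrow(X) <= ncol(X),
           "too few rows (%d) for %d parameters", nrow(X), ncol(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    abort_if(TRUE, "rank-deficient design; aliased column(s): %s",
             paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fml, data = df)
  sm <- suppressWarnings(summary(fit))
  rss <- sum(stats::residuals(fit)^2)
  n <- nrow(df)
  k <- length(stats::coef(fit))
  fstat <- sm$fstatistic
  structure(list(
    lm = fit, outcome = outcome, measures = measures,
    square_terms = squares, covariates = covariates,
    coefficients = coef_table(sm),
    f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    model_p_value = if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    r_squared_adj = sm$adj.r.squared,
    aic = n * log(rss / n) + 2 * k,
    rss = rss, n_used = n, excluded_outliers = excluded,
    n_missing = n_missing, n_total = n_total,
    vif = vif_diagnostics(fit)),
    class = "asy_model_fit")
}

coef_table <- function(sm) {
  ct <- sm$coefficients
  tibble::tibble(term = rownames(ct), estimate = unname(ct[, 1]),
                 std_error = unname(ct[, 2]), statistic = unname(ct[, 3]),
                 p_value = unname(ct[, 4]))
}

# classic variance-inflation factors from the correlation matrix of the
# non-intercept design columns; reported as a collinearity diagnostic only
vif_diagnostics <- function(fit) {
  X <- stats::model.matrix(fit)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  R <- stats::cor(X)
  v <- tryCatch(diag(solve(R)), error = function(e) rep(NA_real_, ncol(X)))
  stats::setNames(v, colnames(X))
}

#' @export
print.asy_model_fit <- function(x, ...) {
  cat(sprintf("Quadratic association model: %s ~ %s\n", x$outcome,
              paste(c(x$measures,
                      if (length(x$square_terms))
                        paste0(x$square_terms, "^2"),
                      x$covariates, "1"), collapse = " + ")))
  cat(sprintf("  n = %d (excluded %d outliers, %d missing), adj R^2 = %.3f, AIC = %.2f\n",
              x$n_used, x$excluded_outliers, x$n_missing,
              x$r_squared_adj, x$aic))
  invisible(x)
}

# admissible term subsets over the measures: each measure contributes
# nothing, its linear term, or linear + square (hierarchy rule: no square
# without its linear term); enumerated smallest-first for deterministic ties
admissible_term_sets <- function(measures) {
  if (length(measures) == 0) {
    return(list(list(lin = character(), sq = character())))
  }
  grid <- expand.grid(rep(list(0:2), length(measures)))
  combos <- lapply(seq_len(nrow(grid)), function(r) {
    lin <- measures[grid[r, ] >= 1]
    sq <- measures[grid[r, ] == 2]
    list(lin = lin, sq = sq)
  })
  combos[order(vapply(combos, function(s) length(s$lin) + length(s$sq), 0))]
}

#' AIC selection over quadratic candidate models
#'
#' Enumerates every admissible subset of measure terms (a squared term is
#' admitted only alongside its linear term), always keeping the covariates,
#' fits each candidate by OLS on the same outlier-screened rows, and returns
#' the fit minimizing the AIC. Ties are broken toward fewer terms, then by
#' enumeration order.
#'
#' @inheritParams fit_quadratic_model
#' @param measures Measure columns whose linear and squared terms form the
#'   candidate space.
#' @return An object of class `asy_model_selection` with elements `best`
#'   (the winning `asy_model_fit`), `selected_terms`, and `candidates`
#'   (a tibble of terms, parameter counts and AICs).
#' @export
aic_select <- function(data, outcome, measures, covariates = character(),
                       iqr_k = 1.5,
                       ref_levels = list(diagnosis = "CN", sex = "F")) {
  cols <- c(outcome, measures, covariates)
  missing_cols <- setdiff(cols, names(data))
  abort_if(length(missing_cols) > 0, "columns not in data: %s",
           paste(missing_cols, collapse = ", "))
  df <- data[stats::complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  if (!is.null(iqr_k)) {
    keep <- suppressWarnings(iqr_filter(df[[outcome]], k = iqr_k))
    df <- df[keep, , drop = FALSE]
  }
  sets <- admissible_term_sets(measures)
  fits <- vector("list", length(sets))
  aics <- numeric(length(sets))
  labels <- character(length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    fits[[i]] <- fit_quadratic_model(
      df, outcome, measures = s$lin, covariates = covariates,
      include_square = s$sq, iqr_k = NULL, ref_levels = ref_levels)
    aics[i] <- fits[[i]]$aic
    labels[i] <- term_label(s)
  }
  best_i <- which.min(aics)  # ties: first index, i.e. fewest terms
  cand <- tibble::tibble(
    terms = labels,
    n_terms = vapply(sets, function(s) length(s$lin) + length(s$sq), 0L),
    aic = aics)
  sel <- sets[[best_i]]
  structure(list(best = fits[[best_i]],
                 selected_terms = c(sel$lin, if (length(sel$sq))
                   sprintf("I(%s^2)", sel$sq)),
                 outcome = outcome, candidates = cand),
            class = "asy_model_selection")
}

term_label <- function(s) {
  terms <- c(s$lin, if (length(s$sq)) sprintf("I(%s^2)", s$sq))
  if (length(terms)) paste(terms, collapse = " + ") else "(covariates only)"
}

#' @export
print.asy_model_selection <- function(x, ...) {
  cat(sprintf("AIC model selection for '%s': selected %s\n", x$outcome,
              if (length(x$selected_terms))
                paste(x$selected_terms, collapse = " + ")
              else "(covariates only)"))
  print(x$best)
  invisible(x)
}

#' Associate network AUCs with outcomes across delays
#'
#' For every outcome and delay, joins the delay's clustering and
#' global-efficiency AUCs to the subject table of the amyloid-positive
#' groups, runs [aic_select()] with the covariates always present, and
#' collects the best model per cell. Model p-values are corrected by
#' Benjamini-Hochberg across the whole outcomes x delays family.
#'
#' @param cohort An `asy_cohort`.
#' @param auc_table Output of [cohort_auc_table()].
#' @param outcomes Metadata columns modelled as dependent variables.
#' @param covariates Covariate columns (default age, sex, education and
#'   diagnosis as cognitive status).
#' @param apoe_covariate Add `apoe4_copies` as a numeric covariate.
#' @param iqr_k Outlier-screen multiplier on each outcome.
#' @param q FDR level for the model p-values.
#' @return A list with `table` (one row per outcome x delay) and `fits`
#'   (the selection objects, named `outcome@delay`).
#' @export
associate_network_measures <- function(cohort, auc_table,
                                       outcomes,
                                       covariates = c("age", "sex",
                                                      "education",
                                                      "diagnosis"),
                                       apoe_covariate = FALSE,
                                       iqr_k = 1.5, q = 0.05) {
  if (apoe_covariate) covariates <- c(covariates, "apoe4_copies")
  subjects <- dplyr::filter(cohort$subjects,
                            .data$group %in% c("CN_Abeta_pos",
                                               "MCI_Abeta_pos",
                                               "AD_Abeta_pos"))
  delays <- sort(unique(auc_table$delay))
  wide <- tidyr::pivot_wider(auc_table,
                             id_cols = c("subject_id", "delay"),
                             names_from = "measure", values_from = "auc")
  names(wide)[names(wide) == "clustering"] <- "clustering_auc"
  names(wide)[names(wide) == "global_efficiency"] <- "global_efficiency_auc"
  measures <- intersect(c("clustering_auc", "global_efficiency_auc"),
                        names(wide))
  rows <- list()
  fits <- list()
  for (oc in outcomes) {
    for (d in delays) {
      df <- dplyr::inner_join(subjects,
                              dplyr::filter(wide, .data$delay == d),
                              by = "subject_id")
      sel <- aic_select(df, oc, measures = measures,
                        covariates = covariates, iqr_k = iqr_k)
      fits[[sprintf("%s@%d", oc, d)]] <- sel
      b <- sel$best
      rows[[length(rows) + 1L]] <- tibble::tibble(
        outcome = oc, delay = d,
        selected_terms = if (length(sel$selected_terms))
          paste(sel$selected_terms, collapse = " + ") else "(covariates only)",
        uses_network_terms = length(sel$selected_terms) > 0,
        r_squared_adj = b$r_squared_adj, f_statistic = b$f_statistic,
        model_p = b$model_p_value, aic = b$aic,
        n_used = b$n_used, excluded_outliers = b$excluded_outliers)
    }
  }
  tbl <- dplyr::bind_rows(rows)
  # an intercept-only winner has no F-test; treat as wholly nonsignificant
  corr <- fdr_bh(ifelse(is.na(tbl$model_p), 1, tbl$model_p), q = q)
  tbl$model_p_fdr <- corr$p_adjusted
  tbl$significant <- corr$rejected
  list(table = tbl, fits = fits)
}
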