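#' Plot a density-sweep measure curve
#'
#' @param object An `asy_measure_curve` from [density_sweep()].
#' @param ... Unused.
#' @return A ggplot: measure value against network density, annotated with
#'   the trapezoidal AUC.
#' @export
autoplot.asy_measure_curve <- function(object, ...) {
  measure <- attr(object, "measure") %||% "measure"
  delay <- attr(object, "delay")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$density, y = .data$value)) +
    ggplot2::geom_area(alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "network density",
      y = gsub("_", " ", measure),
      title = sprintf("%s across the density sweep%s (AUC = %.3f)",
                      gsub("_", " ", measure),
                      if (!is.null(delay)) sprintf(", delay %d", delay) else "",
                      curve_auc(object))) +
    ggplot2::theme_minimal()
}

#' Plot a group-comparison table
#'
#' @param object An `asy_comparison` from [compare_all_groups()].
#' @param ... Unused.
#' @return A ggplot tile map of observed mean differences by contrast and
#'   delay, faceted by measure; FDR-significant cells are starred.
#' @export
autoplot.asy_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$contrast <- paste(df$group_a, "vs", df$group_b)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$delay),
                                   y = .data$contrast,
                                   fill = .data$observed_diff)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 6) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "temporal delay (time steps)", y = NULL,
                  fill = "mean diff",
                  title = "Group differences in AUC (* = FDR-significant)") +
    ggplot2::theme_minimal()
}

#' Plot a connectivity-weight histogram
#'
#' @param object An `asy_weight_hist` from [weight_histogram()].
#' @param ... Unused.
#' @return A ggplot bar chart of the binned nonzero off-diagonal weights.
#' @export
autoplot.asy_weight_hist <- function(object, ...) {
  delay <- attr(object, "delay")
  ggplot2::ggplot(object, ggplot2::aes(
    x = (.data$bin_lower + .data$bin_upper) / 2, y = .data$count)) +
    ggplot2::geom_col(width = if (nrow(object) > 1)
      min(object$bin_upper - object$bin_lower) else 0.01,
      fill = "steelblue") +
    ggplot2::labs(x = "connectivity weight", y = "count",
                  title = if (!is.null(delay))
                    sprintf("Weight distribution, delay %d", delay)
                  else "Weight distribution") +
    ggplot2::theme_minimal()
}

#' Plot observed against fitted values of a quadratic model
#'
#' @param object An `asy_model_fit`.
#' @param ... Unused.
#' @return A ggplot of observed outcome against fitted values with the
#'   identity line.
#' @export
autoplot.asy_model_fit <- function(object, ...) {
  df <- tibble::tibble(fitted = stats::fitted(object$lm),
                       observed = stats::fitted(object$lm) +
                         stats::residuals(object$lm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "fitted", y = "observed",
                  title = sprintf("%s: adj R² = %.3f", object$outcome,
                                  object$r_squared_adj)) +
    ggplot2::theme_minimal()
}
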