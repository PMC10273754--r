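#' Delayed Pearson correlation matrix
#'
#' Correlates every ordered pair of region time series after shifting the
#' follower by `delay` time steps: entry `(i, j)` is the Pearson correlation
#' of region `i` over timepoints `1..(T - delay)` against region `j` over
#' timepoints `(1 + delay)..T`, so the row region leads and the column region
#' follows. Only the `T - delay` overlapping samples are used (no padding or
#' wraparound). At delay 0 this is the ordinary symmetric correlation matrix.
#'
#' @param ts Region-by-timepoint numeric matrix.
#' @param delay Nonnegative integer shift, in time steps.
#' @return Square correlation matrix with attribute `delay`; entries clipped
#'   to `[-1, 1]`. A zero-variance overlap segment yields correlation 0 with
#'   a warning rather than an error.
#' @examples
#' ts <- simulate_var_timeseries(4, 120, seed = 1)
#' C1 <- delayed_correlation(ts, 1)
#' @export
delayed_correlation <- function(ts, delay) {
  abort_if(!is.matrix(ts), "ts must be a matrix (regions x timepoints)")
  abort_if(anyNA(ts), "ts contains missing values")
  delay <- as.integer(delay)
  abort_if(delay < 0, "delay must be nonnegative")
  T_ <- ncol(ts)
  abort_if(delay >= T_ - 2,
           "delay %d too large for %d timepoints (need >= 3 overlapping samples)",
           delay, T_)
  early <- t(ts[, seq_len(T_ - delay), drop = FALSE])
  late <- t(ts[, delay + seq_len(T_ - delay), drop = FALSE])
  sd_e <- apply(early, 2, stats::sd)
  sd_l <- apply(late, 2, stats::sd)
  flat <- sd_e == 0 | sd_l == 0
  if (any(flat)) {
    warning(sprintf(
      "zero-variance overlap segment for region(s) %s; correlations set to 0",
      paste(utils::head(rownames(ts)[flat], 5), collapse = ", ")))
  }
  C <- suppressWarnings(stats::cor(early, late))
  C[!is.finite(C)] <- 0
  C <- pmin(pmax(C, -1), 1)
  labels <- rownames(ts) %||% region_names(nrow(ts))
  dimnames(C) <- list(labels, labels)
  attr(C, "delay") <- delay
  attr(C, "tr_seconds") <- attr(ts, "tr_seconds")
  C
}

#' Symmetric / anti-symmetric decomposition of a square matrix
#'
#' Any square matrix splits uniquely as `C = S + K` with `S = (C + t(C)) / 2`
#' symmetric and `K = (C - t(C)) / 2` anti-symmetric. Applied to a delayed
#' correlation matrix, `S` carries the undirected coupling and `K` the
#' directional excess: `K[i, j] > 0` means region `i` leads region `j` at this
#' delay. At delay 0 the matrix is symmetric, so `K` vanishes and the method
#' is informative only at delay >= 1.
#'
#' @param C Square numeric matrix.
#' @return A list with components `S` and `K`; attributes `delay` and
#'   `tr_seconds` of `C` are carried onto both parts.
#' @examples
#' d <- antisymmetric_decomposition(matrix(c(1, 0.1, 0.5, 1), 2))
#' d$S + d$K
#' @export
antisymmetric_decomposition <- function(C) {
  abort_if(!is_square(C), "input must be a square matrix")
  S <- (C + t(C)) / 2
  K <- (C - t(C)) / 2
  for (a in c("delay", "tr_seconds")) {
    attr(S, a) <- attr(C, a)
    attr(K, a) <- attr(C, a)
  }
  list(S = S, K = K)
}

#' Directed weighted network from an anti-symmetric matrix
#'
#' Keeps the positive entries of the anti-symmetric part as directed edge
#' weights (negative entries are the mirror image of positive ones and are
#' set to zero), so at most one of the `(i, j)` / `(j, i)` pair carries
#' weight and a positive `W[i, j]` encodes the directed connection
#' `i -> j` (row = earlier/source, column = later/target).
#'
#' @param K Anti-symmetric matrix (checked to tolerance `1e-8`).
#' @param delay Delay label for the network; defaults to `attr(K, "delay")`.
#' @return Nonnegative weight matrix of class `asy_network` with zero
#'   diagonal and attribute `delay`.
#' @export
build_directed_network <- function(K, delay = attr(K, "delay")) {
  abort_if(!is_square(K), "input must be a square matrix")
  dev <- max(abs(K + t(K)))
  abort_if(dev > 1e-8,
           "matrix is not anti-symmetric: max |K + t(K)| = %.3g", dev)
  W <- pmax(K, 0)
  diag(W) <- 0
  attr(W, "delay") <- delay
  attr(W, "tr_seconds") <- attr(K, "tr_seconds")
  class(W) <- c("asy_network", class(W))
  W
}

#' Element-wise mean of a group's directed networks
#'
#' Averages individual weight matrices into a representative network for a
#' group. Because different subjects may orient the same pair differently,
#' the average can carry weight on both `(i, j)` and `(j, i)`; it is returned
#' as a plain matrix flagged `"average"` rather than an `asy_network`.
#'
#' @param networks List of weight matrices of identical shape and delay.
#' @return The mean weight matrix with attributes `delay` and `kind =
#'   "average"`.
#' @export
group_average_network <- function(networks) {
  abort_if(length(networks) == 0, "empty network collection")
  dims <- vapply(networks, function(w) dim(w), integer(2))
  abort_if(any(dims != dims[, 1]), "networks differ in shape")
  delays <- unique(unlist(lapply(networks, attr, "delay")))
  abort_if(length(delays) > 1, "networks differ in delay")
  avg <- Reduce(`+`, lapply(networks, unclass)) / length(networks)
  attr(avg, "delay") <- if (length(delays)) delays else NULL
  attr(avg, "kind") <- "average"
  avg
}

#' Histogram of connectivity weights
#'
#' Bins the nonzero off-diagonal entries of a weight matrix (exact zeros are
#' structural absences created by negativity-zeroing, not weights, and are
#' excluded). Used to inspect how weight distributions narrow as the temporal
#' delay grows.
#'
#' @param matrix Square numeric matrix.
#' @param n_bins Number of equal-width bins over the range of included
#'   values.
#' @return A tibble of class `asy_weight_hist` with columns `bin_lower`,
#'   `bin_upper`, `count`; counts sum to the number of nonzero off-diagonal
#'   entries.
#' @export
weight_histogram <- function(matrix, n_bins = 30) {
  abort_if(!is_square(matrix), "input must be a square matrix")
  abort_if(n_bins < 1, "n_bins must be >= 1")
  v <- matrix[row(matrix) != col(matrix)]
  v <- v[v != 0]
  if (length(v) == 0) {
    out <- tibble::tibble(bin_lower = numeric(), bin_upper = numeric(),
                          count = integer())
  } else if (min(v) == max(v)) {
    out <- tibble::tibble(bin_lower = min(v), bin_upper = max(v),
                          count = length(v))
  } else {
    breaks <- seq(min(v), max(v), length.out = n_bins + 1)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    out <- tibble::tibble(bin_lower = utils::head(h$breaks, -1),
                          bin_upper = h$breaks[-1],
                          count = h$counts)
  }
  class(out) <- c("asy_weight_hist", class(out))
  attr(out, "delay") <- attr(matrix, "delay")
  out
}
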