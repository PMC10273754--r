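#' Binarize a directed weighted network at a proportional density
#'
#' Keeps the `m = round(density * n * (n - 1))` largest positive weights as
#' directed edges. Ties at the cut are broken deterministically by ascending
#' (row, column) index. When fewer than `m` positive weights exist, all of
#' them are kept and the achieved density is recorded with a warning — an
#' anti-symmetric-derived network can carry weight on at most half of the
#' ordered pairs, so requested densities above 0.5 are never achievable.
#'
#' @param W Nonnegative weight matrix (e.g. from [build_directed_network()]).
#' @param density Target edge density in `(0, 1]`, as a fraction of the
#'   `n * (n - 1)` possible directed edges.
#' @return A binary adjacency matrix of class `asy_binary_graph` with
#'   attributes `density` (requested) and `density_achieved`.
#' @export
threshold_by_density <- function(W, density) {
  abort_if(!is_square(W), "W must be a square matrix")
  abort_if(density <= 0 || density > 1, "density must be in (0, 1]")
  n <- nrow(W)
  m <- round(density * n * (n - 1))
  ord <- edge_order(W)
  n_pos <- length(ord)
  if (n_pos < m) {
    warning(sprintf(
      "only %d positive weights available for %d requested edges; achieved density %.4f",
      n_pos, m, n_pos / (n * (n - 1))))
  }
  keep <- utils::head(ord, min(m, n_pos))
  A <- matrix(0L, n, n, dimnames = dimnames(W))
  A[keep] <- 1L
  attr(A, "density") <- density
  attr(A, "density_achieved") <- length(keep) / (n * (n - 1))
  attr(A, "delay") <- attr(W, "delay")
  class(A) <- c("asy_binary_graph", class(A))
  A
}

# linear indices of positive off-diagonal weights, strongest first, ties by
# ascending (row, column)
edge_order <- function(W) {
  W <- unclass(W)
  idx <- which(W > 0 & row(W) != col(W))
  if (length(idx) == 0) return(integer())
  r <- (idx - 1L) %% nrow(W) + 1L
  cc <- (idx - 1L) %/% nrow(W) + 1L
  idx[order(-W[idx], r, cc)]
}

check_binary <- function(A) {
  abort_if(!is_square(A), "adjacency must be a square matrix")
  A <- unclass(A)
  abort_if(any(diag(A) != 0), "adjacency diagonal must be zero")
  abort_if(!all(A %in% c(0, 1)), "adjacency must be binary")
  A
}

#' Binary directed clustering coefficient
#'
#' Fagiolo's generalization of the clustering coefficient to binary directed
#' graphs: for node `i`, the number of directed triangles of any orientation
#' is `t_i = ((A + t(A))^3)[i, i] / 2`, and the normalization counts the
#' possible triangles from the total degree `d_i = sum_j (A[i,j] + A[j,i])`
#' minus twice the reciprocal degree `d_i^rec = sum_j A[i,j] A[j,i]`. Nodes
#' whose denominator is zero contribute 0. Returns the mean over nodes — the
#' fraction of closed triangles around a node, a segregation measure.
#'
#' @param G Binary adjacency matrix with zero diagonal.
#' @return Scalar in `[0, 1]`.
#' @examples
#' cyc3 <- matrix(0, 3, 3); cyc3[cbind(1:3, c(2, 3, 1))] <- 1
#' clustering_coefficient(cyc3)  # 0.5
#' @export
clustering_coefficient <- function(G) {
  A <- check_binary(G)
  n <- nrow(A)
  if (n < 3) return(0)
  M <- A + t(A)
  t_i <- diag(M %*% M %*% M) / 2
  d_tot <- rowSums(A) + colSums(A)
  d_rec <- diag(A %*% A)
  denom <- d_tot * (d_tot - 1) - 2 * d_rec
  ci <- ifelse(denom > 0, t_i / denom, 0)
  mean(ci)
}

#' Binary directed global efficiency
#'
#' Mean inverse directed shortest-path length over ordered node pairs, with
#' unreachable pairs contributing 0 (`1 / Inf`). Paths are unweighted
#' (breadth-first). An integration measure: it grows as paths between any two
#' nodes shorten.
#'
#' @param G Binary adjacency matrix with zero diagonal.
#' @return Scalar in `[0, 1]`.
#' @examples
#' cyc4 <- matrix(0, 4, 4); cyc4[cbind(1:4, c(2, 3, 4, 1))] <- 1
#' global_efficiency(cyc4)  # 11/18
#' @export
global_efficiency <- function(G) {
  A <- check_binary(G)
  n <- nrow(A)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  D <- igraph::distances(g, mode = "out")
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

measure_functions <- list(clustering = clustering_coefficient,
                          global_efficiency = global_efficiency)

#' Graph measure across a density sweep
#'
#' Thresholds a weighted directed network at every density from `d_min` to
#' `d_max` in steps of `step` (46 points at the defaults 0.05, 0.50, 0.01)
#' and evaluates the requested measure on each binary graph. Edge sets are
#' nested across the sweep, so global efficiency is non-decreasing in
#' density.
#'
#' @param W Nonnegative weight matrix.
#' @param measure `"clustering"` or `"global_efficiency"`.
#' @param d_min,d_max,step Density grid (fractions in `(0, 1]`).
#' @return A tibble of class `asy_measure_curve` with columns `density` and
#'   `value`, and attributes `measure` and `delay`.
#' @export
density_sweep <- function(W, measure = c("clustering", "global_efficiency"),
                          d_min = 0.05, d_max = 0.50, step = 0.01) {
  measure <- match.arg(measure)
  abort_if(d_min <= 0 || d_min >= d_max || d_max > 1, "need 0 < d_min < d_max <= 1")
  abort_if(step <= 0, "step must be > 0")
  densities <- round(seq(d_min, d_max, by = step), 10)
  fn <- measure_functions[[measure]]
  n <- nrow(W)
  ord <- edge_order(W)
  base <- matrix(0L, n, n, dimnames = dimnames(W))
  short <- FALSE
  values <- vapply(densities, function(d) {
    m <- round(d * n * (n - 1))
    if (length(ord) < m) short <<- TRUE
    A <- base
    A[utils::head(ord, min(m, length(ord)))] <- 1L
    fn(A)
  }, numeric(1))
  if (short) {
    warning("fewer positive weights than requested at the top of the sweep; achieved densities recorded")
  }
  out <- tibble::tibble(density = densities, value = values)
  class(out) <- c("asy_measure_curve", class(out))
  attr(out, "measure") <- measure
  attr(out, "delay") <- attr(W, "delay")
  out
}

#' Area under a density-sweep measure curve
#'
#' Trapezoidal integral of the measure values against density (as a
#' fraction), summarizing a curve by one scalar per subject, measure and
#' delay and removing the dependence on any single threshold. A constant
#' value `c` over the default range integrates to `0.45 * c`.
#'
#' @param curve An `asy_measure_curve` (or any data frame with `density` and
#'   `value` columns, densities strictly increasing).
#' @return Scalar AUC.
#' @export
curve_auc <- function(curve) {
  d <- curve$density
  v <- curve$value
  abort_if(length(d) < 2, "need at least 2 points to integrate")
  abort_if(any(diff(d) <= 0), "densities must be strictly increasing")
  sum(diff(d) * (utils::head(v, -1) + v[-1]) / 2)
}

#' Per-subject AUC table for a cohort
#'
#' Runs the full connectivity pipeline for every subject and delay — delayed
#' correlation, anti-symmetric decomposition, directed network, density
#' sweep, AUC — and collects the results in a long table, the unit of all
#' downstream group statistics.
#'
#' @param cohort An `asy_cohort` (simulated or read from disk).
#' @param delays Positive integer delays (delay 0 is refused: the
#'   anti-symmetric part of a zero-lag correlation matrix is identically
#'   zero).
#' @param measures Subset of `c("clustering", "global_efficiency")`.
#' @param d_min,d_max,step Density grid passed to [density_sweep()].
#' @param verbose Emit a progress message every 10 subjects.
#' @return A tibble with columns `subject_id`, `group`, `delay`, `measure`,
#'   `auc`.
#' @export
cohort_auc_table <- function(cohort, delays = 1:5,
                             measures = c("clustering", "global_efficiency"),
                             d_min = 0.05, d_max = 0.50, step = 0.01,
                             verbose = FALSE) {
  abort_if(any(delays < 1), "delays must be >= 1 (anti-symmetric part vanishes at delay 0)")
  measures <- match.arg(measures, several.ok = TRUE)
  ids <- cohort$subjects$subject_id
  rows <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    id <- ids[s]
    ts <- cohort$timeseries[[id]]
    sub_rows <- list()
    for (d in delays) {
      K <- antisymmetric_decomposition(delayed_correlation(ts, d))$K
      W <- build_directed_network(K, delay = d)
      for (ms in measures) {
        crv <- density_sweep(W, ms, d_min = d_min, d_max = d_max, step = step)
        sub_rows[[length(sub_rows) + 1L]] <-
          tibble::tibble(subject_id = id, delay = d, measure = ms,
                         auc = curve_auc(crv))
      }
    }
    rows[[s]] <- dplyr::bind_rows(sub_rows)
    if (verbose && s %% 10 == 0) {
      message(sprintf("processed %d / %d subjects", s, length(ids)))
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(out,
                   dplyr::select(cohort$subjects, "subject_id", "group"),
                   by = "subject_id") |>
    dplyr::relocate("group", .after = "subject_id")
}
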