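#' Directed lagged couplings between regions
#'
#' A coupling table is the generative counterpart of a directed functional
#' connection: the source region drives the target region `lag` time steps
#' later with the given coefficient. `couplings()` builds and validates such a
#' table; `coupling_spectral_radius()` reports the spectral radius of the
#' companion matrix of the implied vector autoregression, which must be below
#' one for the process to be stationary.
#'
#' @param source,target Integer region indices (1-based); `source != target`.
#' @param lag Positive integer delay, in time steps (one step = one repetition
#'   time of the scan).
#' @param strength Real coupling coefficients.
#' @return A tibble with columns `source`, `target`, `lag`, `strength`.
#' @examples
#' cp <- couplings(source = 1, target = 2, lag = 2, strength = 0.6)
#' coupling_spectral_radius(cp, n_regions = 2)
#' @export
couplings <- function(source = integer(), target = integer(),
                      lag = integer(), strength = numeric()) {
  tbl <- tibble::tibble(
    source = as.integer(source), target = as.integer(target),
    lag = as.integer(lag), strength = as.numeric(strength)
  )
  validate_couplings(tbl)
}

validate_couplings <- function(tbl, n_regions = NULL) {
  abort_if(!all(c("source", "target", "lag", "strength") %in% names(tbl)),
           "couplings need columns source, target, lag, strength")
  abort_if(any(tbl$source == tbl$target),
           "self-couplings (source == target) are not allowed")
  abort_if(nrow(tbl) > 0 && any(tbl$lag < 1L), "coupling lags must be >= 1")
  if (!is.null(n_regions)) {
    abort_if(nrow(tbl) > 0 &&
               any(c(tbl$source, tbl$target) < 1L |
                     c(tbl$source, tbl$target) > n_regions),
             "coupling indices outside 1..%d", n_regions)
  }
  tibble::as_tibble(tbl)
}

# Lag-indexed list of n x n coefficient matrices B_l with
# B_l[target, source] = strength; `ar1` adds a diagonal AR(1) term at lag 1.
coupling_matrices <- function(couplings, n_regions, ar1 = 0) {
  n_lags <- max(c(if (nrow(couplings)) max(couplings$lag) else 0L,
                  if (ar1 != 0) 1L else 0L))
  B <- lapply(seq_len(n_lags), function(l) matrix(0, n_regions, n_regions))
  for (r in seq_len(nrow(couplings))) {
    l <- couplings$lag[r]
    B[[l]][couplings$target[r], couplings$source[r]] <-
      B[[l]][couplings$target[r], couplings$source[r]] + couplings$strength[r]
  }
  if (ar1 != 0) diag(B[[1]]) <- diag(B[[1]]) + ar1
  B
}

#' @rdname couplings
#' @param couplings A coupling table as returned by [couplings()].
#' @param n_regions Number of regions in the process.
#' @param ar1 Optional common first-order autoregressive coefficient applied to
#'   every region's own past (models temporal autocorrelation of the signal);
#'   it enters the stability check together with the cross-region couplings.
#' @export
coupling_spectral_radius <- function(couplings, n_regions, ar1 = 0) {
  couplings <- validate_couplings(couplings, n_regions)
  B <- coupling_matrices(couplings, n_regions, ar1 = ar1)
  if (length(B) == 0) return(0)
  L <- length(B)
  comp <- matrix(0, n_regions * L, n_regions * L)
  comp[seq_len(n_regions), ] <- do.call(cbind, B)
  if (L > 1) {
    idx <- seq_len(n_regions * (L - 1))
    comp[cbind(n_regions + idx, idx)] <- 1
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Modular backbone of lagged couplings
#'
#' Generates a community-structured coupling template: regions are split into
#' `n_modules` equal modules and every region receives, per lag, `k_within`
#' couplings to random regions of its own module and `k_between` couplings to
#' random regions of other modules. Coupling signs are random (balanced), so
#' the common activity mode does not accumulate and much denser backbones
#' remain stable than with all-positive couplings; a negative coupling simply
#' orients the resulting directed edge the other way round, leaving the pair
#' topology intact. The ratio of between- to within-module couplings is the
#' main group lever: integrated backbones (large `k_between`) produce high
#' global efficiency throughout the density sweep, segregated ones
#' (`k_between` near 0) leave inter-module pairs connected only through
#' noise-level weights and depress efficiency persistently.
#'
#' @param n_regions Number of regions (split as evenly as possible).
#' @param n_modules Number of modules (>= 2).
#' @param k_within,k_between Couplings per region per lag, inside and across
#'   modules (`k_between` may be 0).
#' @param lags Integer lags over which the backbone is replicated.
#' @param strength Absolute coupling coefficient; signs are drawn at random.
#' @param seed Optional integer seed.
#' @return A coupling tibble (see [couplings()]).
#' @export
modular_couplings <- function(n_regions, n_modules = 3, k_within = 4,
                              k_between = 1, lags = 1:2, strength = 0.2,
                              seed = NULL) {
  abort_if(n_modules < 2, "need at least 2 modules")
  abort_if(n_regions < 2 * n_modules, "n_regions too small for %d modules",
           n_modules)
  module <- rep(seq_len(n_modules), length.out = n_regions)[
    order(rep(seq_len(n_modules), length.out = n_regions))]
  module <- sort(module)
  maybe_with_seed(seed, {
    rows <- list()
    for (l in lags) {
      for (i in seq_len(n_regions)) {
        own <- setdiff(which(module == module[i]), i)
        oth <- which(module != module[i])
        tw <- sample(own, min(k_within, length(own)))
        tb <- if (k_between > 0) sample(oth, min(k_between, length(oth)))
              else integer()
        for (j in c(tw, tb)) {
          rows[[length(rows) + 1L]] <- c(source = i, target = j, lag = l)
        }
      }
    }
    tbl <- tibble::as_tibble(do.call(rbind, rows))
    tbl$strength <- strength * sample(c(-1, 1), nrow(tbl), replace = TRUE)
    tbl <- dplyr::distinct(tbl, .data$source, .data$target, .data$lag,
                           .keep_all = TRUE)
    validate_couplings(tbl, n_regions)
  })
}

#' Hub-concentrated ring backbone of lagged couplings
#'
#' The default group-template family of the synthetic cohort. Per lag, it
#' draws `edges_per_lag` directed couplings whose sources cycle over the
#' first `n_sources` regions; each edge's target is the source's clockwise
#' ring neighbour with probability `ring_prob`, otherwise a uniformly random
#' other region. Two parameters shape the thresholded-network topology:
#' `n_sources` concentrates out-going couplings onto fewer hub regions
#' (leaving many regions without strong afferents, which depresses global
#' efficiency throughout the density sweep), and `ring_prob` trades regular
#' coherent propagation against random shortcuts. If the resulting process,
#' including the `ar1` term it will be simulated with, has companion
#' spectral radius above `max_radius`, all strengths are rescaled onto that
#' margin so every template is simulable.
#'
#' @param n_regions Number of regions.
#' @param n_sources Number of distinct source regions (1..n_regions).
#' @param ring_prob Probability that an edge targets the ring neighbour.
#' @param edges_per_lag Couplings drawn per lag (default `n_regions`).
#' @param lags Integer lags over which the backbone is replicated.
#' @param strength Coupling coefficient (rescaled if unstable); a length-2
#'   vector gives a uniform range of per-edge magnitudes, which produces the
#'   broad structural weight distributions seen at short delays.
#' @param sign_mix Draw random coupling signs (balanced). Mixed signs cancel
#'   the common activity mode, allowing much denser stable backbones; a
#'   negative coupling orients its directed edge the other way round.
#' @param seed Optional integer seed.
#' @param max_radius Stability margin for the rescaling guard.
#' @param ar1 AR(1) coefficient assumed for the stability check.
#' @return A coupling tibble (see [couplings()]).
#' @export
hub_ring_couplings <- function(n_regions, n_sources = n_regions,
                               ring_prob = 0.2,
                               edges_per_lag = n_regions, lags = 1:2,
                               strength = 0.28, sign_mix = FALSE,
                               seed = NULL,
                               max_radius = 0.9, ar1 = 0.3) {
  abort_if(n_sources < 1 || n_sources > n_regions,
           "n_sources must be in 1..n_regions")
  maybe_with_seed(seed, {
    rows <- list()
    for (l in lags) {
      src <- rep(seq_len(n_sources), length.out = edges_per_lag)
      for (i in src) {
        j <- if (stats::runif(1) < ring_prob) (i %% n_regions) + 1L
             else sample(setdiff(seq_len(n_regions), i), 1L)
        rows[[length(rows) + 1L]] <- c(source = i, target = j, lag = l)
      }
    }
    tbl <- tibble::as_tibble(do.call(rbind, rows))
    tbl$strength <- if (length(strength) == 2)
      stats::runif(nrow(tbl), strength[1], strength[2]) else strength
    if (sign_mix) {
      tbl$strength <- tbl$strength *
        sample(c(-1, 1), nrow(tbl), replace = TRUE)
    }
    tbl <- dplyr::distinct(tbl, .data$source, .data$target, .data$lag,
                           .keep_all = TRUE)
    # radius is not linear in the strengths once ar1 is fixed; iterate
    for (it in 1:8) {
      rho <- coupling_spectral_radius(tbl, n_regions, ar1 = ar1)
      if (rho <= max_radius) break
      tbl$strength <- tbl$strength * max(0.6, max_radius / rho)
    }
    validate_couplings(tbl, n_regions)
  })
}

#' Small-world backbone of lagged couplings
#'
#' Generates a directed ring-lattice backbone over the regions — for each lag
#' in `lags`, every region drives its next `k_out` clockwise neighbours — and
#' rewires each edge's target uniformly at random with probability
#' `rewire_prob`. Low rewiring yields long average directed paths (low global
#' efficiency after thresholding); high rewiring yields shortcut-rich,
#' integrated topology. Groups of a cohort design differ mainly in this
#' parameter.
#'
#' @param n_regions Number of regions.
#' @param k_out Out-neighbours per region per lag.
#' @param lags Integer lags over which the backbone is replicated.
#' @param rewire_prob Probability of rewiring each edge's target.
#' @param strength Coupling coefficient shared by all edges. Keep
#'   `k_out * length(lags) * strength` (+ any `ar1`) comfortably below 1 for
#'   stability.
#' @param seed Optional integer seed for the rewiring draws.
#' @return A coupling tibble (see [couplings()]).
#' @export
small_world_couplings <- function(n_regions, k_out = 2, lags = 1:2,
                                  rewire_prob = 0.2, strength = 0.15,
                                  seed = NULL) {
  abort_if(n_regions < k_out + 2, "n_regions too small for k_out = %d", k_out)
  maybe_with_seed(seed, {
    rows <- list()
    for (li in seq_along(lags)) {
      for (i in seq_len(n_regions)) {
        # offsets staggered by lag so each lag's sub-backbone is distinct
        offs <- ((li - 1L) * k_out + seq_len(k_out))
        for (o in offs) {
          j <- ((i - 1L + o) %% n_regions) + 1L
          if (stats::runif(1) < rewire_prob) {
            j <- sample(setdiff(seq_len(n_regions), i), 1L)
          }
          rows[[length(rows) + 1L]] <-
            c(source = i, target = j, lag = lags[li])
        }
      }
    }
    tbl <- tibble::as_tibble(do.call(rbind, rows))
    tbl$strength <- strength
    # drop duplicate (source, target, lag) created by rewiring collisions
    tbl <- dplyr::distinct(tbl, .data$source, .data$target, .data$lag,
                           .keep_all = TRUE)
    validate_couplings(tbl, n_regions)
  })
}
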