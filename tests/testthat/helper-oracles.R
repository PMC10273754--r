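# Independent oracles used to pin down the implementation's semantics.
# These re-derive each quantity from first principles (triple loops,
# Floyd-Warshall, exhaustive enumeration) and must stay free of any call
# into the code paths they check.

# directed clustering via explicit triangle-pattern counting: for node i,
# half the number of ordered (j, h) pairs closing a triangle in the
# symmetrized multigraph, normalized by the possible triangles
oracle_clustering <- function(A) {
  n <- nrow(A)
  if (n < 3) return(0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (i == j || i == h || j == h) next
      t_i <- t_i + (A[i, j] + A[j, i]) * (A[i, h] + A[h, i]) *
        (A[j, h] + A[h, j])
    }
    t_i <- t_i / 2
    d_tot <- sum(A[i, ]) + sum(A[, i])
    d_rec <- sum(A[i, ] * A[, i])
    denom <- d_tot * (d_tot - 1) - 2 * d_rec
    ci[i] <- if (denom > 0) t_i / denom else 0
  }
  mean(ci)
}

# global efficiency via Floyd-Warshall all-pairs shortest paths
oracle_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

# Benjamini-Hochberg by the literal step-up definition
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rejected <- logical(m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  adj <- numeric(m)
  adj[ord] <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  list(rejected = rejected, adjusted = adj)
}

# exact two-sided permutation p-value by enumerating all label splits
oracle_perm_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- mean(a) - mean(b)
  splits <- utils::combn(length(pooled), na)
  stats <- apply(splits, 2, function(ix) {
    mean(pooled[ix]) - mean(pooled[-ix])
  })
  mean(abs(stats) >= abs(obs) - 1e-12 * max(1, abs(obs)))
}

# trapezoid integral recomputed as a midpoint Riemann sum with many
# substeps per knot interval (exact for the piecewise-linear interpolant)
oracle_riemann_auc <- function(density, value, n_sub = 256) {
  total <- 0
  for (i in seq_len(length(density) - 1)) {
    h <- (density[i + 1] - density[i]) / n_sub
    mids <- density[i] + (seq_len(n_sub) - 0.5) * h
    ys <- value[i] + (value[i + 1] - value[i]) *
      (mids - density[i]) / (density[i + 1] - density[i])
    total <- total + sum(ys) * h
  }
  total
}

# all binary directed adjacency matrices on n nodes (zero diagonal)
all_digraphs <- function(n) {
  off <- which(row(diag(n)) != col(diag(n)))
  n_bits <- length(off)
  lapply(seq_len(2^n_bits) - 1L, function(code) {
    A <- matrix(0L, n, n)
    A[off] <- as.integer(intToBits(code)[seq_len(n_bits)])
    A
  })
}
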