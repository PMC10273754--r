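# Small cohorts and graphs built in code at test time.

tiny_cohort <- function(seed = 1, n_regions = 12, n_timepoints = 100,
                        n_per_group = c(4, 4, 4, 4)) {
  des <- default_cohort_design(seed = seed, n_regions = n_regions,
                               n_per_group = n_per_group)
  simulate_cohort(des$groups, n_regions, n_timepoints, seed = seed,
                  jitter_sd = des$params$jitter_sd, ar1 = des$params$ar1)
}

digraph_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  if (length(edges)) A[do.call(rbind, edges)] <- 1L
  A
}

complete_digraph <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

directed_cycle <- function(n) {
  digraph_from_edges(n, lapply(seq_len(n), function(i) {
    c(i, i %% n + 1L)
  }))
}

exit_status <- function(x) {
  s <- attr(x, "status")
  if (is.null(s)) 0L else s
}

random_weighted_network <- function(n, seed) {
  withr::with_seed(seed, {
    K <- matrix(stats::rnorm(n * n), n, n)
    K <- (K - t(K)) / 2
    build_directed_network(K, delay = 1L)
  })
}
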