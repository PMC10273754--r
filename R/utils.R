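# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state when `seed` is given, restoring the
# caller's RNG afterwards; with seed = NULL the ambient RNG stream is used.
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

region_names <- function(n) sprintf("R%03d", seq_len(n))

#' @importFrom rlang .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
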