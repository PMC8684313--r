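# Small shared helpers: classed errors, seeded evaluation, numeric utilities.

occ_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "occrnn_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Wrapper around [withr::with_seed()] so that every seeded operation in the
#' package restores the caller's RNG state.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# argmax with ties broken toward the lowest index; returns 0-based class index
argmax0 <- function(x) which.max(x) - 1L

# row-wise argmax for a matrix of scores, 0-based
row_argmax0 <- function(m) max.col(m, ties.method = "first") - 1L

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a stream of sub-seeds from one master seed (kept < 2^31)
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
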