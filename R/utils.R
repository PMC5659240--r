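#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded helpers do not perturb an enclosing random sequence.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a stage-specific sub-seed from a run seed
#'
#' Deterministic mixing of a master seed and a stage offset, kept within
#' 32-bit integer range, so independent stages of one run draw from
#' decoupled streams.
#'
#' @param seed master integer seed.
#' @param offset nonnegative integer stage identifier.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  as.integer((abs(seed) * 48271 + offset * 16807 + 7) %% 2147483629)
}

# stop() with a consistent prefix for user input problems
input_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
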