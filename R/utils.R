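#' Evaluate an expression under a local random seed
#'
#' Runs `expr` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so library functions can be reproducible without clobbering the
#' global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Randomness flows from one master seed; each operation draws its own
#' substream via a fixed offset so that changing one stage does not shift
#' the random numbers used by another. Kept below 2^31 - 1.
#'
#' @param seed Master integer seed (or `NULL`, passed through).
#' @param offset Integer offset identifying the substream.
#' @return An integer seed, or `NULL` if `seed` is `NULL`.
#' @keywords internal
sub_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647L)
}

#' Numerically stable log-sum-exp
#' @param x Numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
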