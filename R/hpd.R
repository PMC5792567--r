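#' Highest posterior density interval from samples
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' samples (the Chen-Shao empirical algorithm). Ties between equally short
#' windows are broken toward the first window in sorted order.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rnorm(1e4), 0.95)
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 2L) stop("need >= 2 samples", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("'mass' must be in (0, 1)", call. = FALSE)
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)  # which.min returns the first minimum
  c(lower = s[i], upper = s[i + m - 1])
}

#' Random subsample of posterior draws
#'
#' Uniform subset without replacement, reproducible under a seed; the
#' working summaries downstream (correlation analyses, uncertainty grid)
#' consume these draws rather than full chains.
#'
#' @param samples Numeric vector.
#' @param n Number of draws to keep (<= `length(samples)`).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
subsample_draws <- function(samples, n, seed = NULL) {
  if (n > length(samples)) {
    stop("'n' exceeds the number of available samples", call. = FALSE)
  }
  with_seed(seed, samples[sample.int(length(samples), n)])
}
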