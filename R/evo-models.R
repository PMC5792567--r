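#' @name evo-models
#' @title Maximum-likelihood models of continuous-trait evolution
#'
#' @description
#' Fits of three single-trait models on a fixed tree, used to ask whether a
#' trait (or climatic-niche variable) carries phylogenetic signal and
#' whether its variance is constrained:
#' * Brownian motion (BM): variance grows linearly along branches at rate
#'   sigma^2; parameters sigma^2 and root state z0 (k = 2).
#' * Ornstein-Uhlenbeck (OU): BM with attraction of strength alpha toward
#'   an optimum; the fixed-root (non-stationary) covariance is used so
#'   non-ultrametric trees are handled; parameters alpha, sigma^2, z0
#'   (k = 3). alpha -> 0 recovers BM; large alpha approaches white noise
#'   on an ultrametric tree.
#' * White noise (WN): iid normal tip values, no signal; parameters mean
#'   and sigma^2 (k = 2).
#'
#' sigma^2 and z0 are profiled analytically by generalised least squares;
#' only alpha is optimised numerically (grid scan plus bounded
#' golden-section refinement, tolerance 1e-8).
NULL

new_evo_fit <- function(model, logL, k, n, params) {
  structure(list(model = model, logL = logL, k = k, n = n,
                 aicc = if (n > k + 1 && is.finite(logL))
                   aicc(logL, k, n) else NA_real_,
                 params = params),
            class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.4f, k = %d, n = %d, AICc = %.4f\n",
              x$model, x$logL, x$k, x$n, x$aicc))
  cat("params:", paste(names(x$params),
                       signif(unlist(x$params), 5), sep = " = ",
                       collapse = ", "), "\n")
  invisible(x)
}

# GLS profile of (z0, sigma2) for unit-rate covariance V0; returns the
# maximised log-likelihood and estimates.
gls_profile <- function(x, V0) {
  n <- length(x)
  L <- tryCatch(chol(V0), error = function(e) {
    stop("singular phylogenetic covariance (zero-length tree?)",
         call. = FALSE)
  })
  iV <- chol2inv(L)
  logdet <- 2 * sum(log(diag(L)))
  one <- rep(1, n)
  a <- sum(iV)
  z0 <- sum(iV %*% x) / a
  r <- x - z0
  s2 <- drop(crossprod(r, iV %*% r)) / n
  if (s2 <= 0) {
    warning("zero variance after GLS centring; degenerate fit",
            call. = FALSE)
    return(list(z0 = z0, s2 = 0, logL = Inf, degenerate = TRUE))
  }
  logL <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
  list(z0 = z0, s2 = s2, logL = logL, degenerate = FALSE)
}

match_tip_data <- function(x, tree) {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label)) {
      stop("'x' must be named by taxa or have one value per tip",
           call. = FALSE)
    }
    names(x) <- tree$tip.label
  }
  x <- x[!is.na(x)]
  keep <- intersect(tree$tip.label, names(x))
  if (length(keep) < 2L) stop("fewer than 2 tips with data", call. = FALSE)
  if (length(keep) < length(tree$tip.label)) {
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, keep))
  }
  list(x = x[tree$tip.label], tree = tree)
}

#' Fit Brownian motion to one trait
#'
#' @param x Named numeric vector of tip values (names = taxa); tips without
#'   data are pruned.
#' @param tree A `phylo` object.
#' @return An `evo_fit` with ML estimates `sigma2` (rate) and `z0` (root
#'   state). `sigma2` uses the ML divisor n.
#' @export
fit_bm <- function(x, tree) {
  m <- match_tip_data(x, tree)
  C <- phylo_vcv(m$tree)
  g <- gls_profile(m$x, C)
  new_evo_fit("BM", g$logL, 2L, length(m$x),
              list(sigma2 = g$s2, z0 = g$z0))
}

#' Fit a white-noise (iid normal) model
#'
#' @param x Numeric vector of tip values (>= 2).
#' @return An `evo_fit` with `mean` and ML variance `sigma2` (divisor n).
#' @export
fit_wn <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("need >= 2 values", call. = FALSE)
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) {
    warning("constant data; degenerate white-noise fit", call. = FALSE)
    return(new_evo_fit("WN", Inf, 2L, n, list(mean = mu, sigma2 = 0)))
  }
  logL <- -0.5 * n * (log(2 * pi * s2) + 1)
  new_evo_fit("WN", logL, 2L, n, list(mean = mu, sigma2 = s2))
}

# Unit-rate OU covariance with fixed root: for tips i, j with shared depth
# t_ij and patristic distance d_ij,
#   V_ij = exp(-alpha d_ij) (1 - exp(-2 alpha t_ij)) / (2 alpha),
# which tends to the BM covariance t_ij as alpha -> 0.
ou_v0 <- function(td, alpha) {
  if (alpha <= 0) return(td$C)
  exp(-alpha * td$D) * (-expm1(-2 * alpha * td$C)) / (2 * alpha)
}

#' Fit an Ornstein-Uhlenbeck model to one trait
#'
#' Profiles sigma^2 and z0 analytically and optimises the selection
#' strength alpha within `alpha_bounds` (a coarse log-spaced scan followed
#' by bounded optimisation, so local optima near the BM boundary are not
#' missed).
#'
#' @inheritParams fit_bm
#' @param alpha_bounds Length-2 numeric, bounds for alpha (default 0-1000).
#' @return An `evo_fit` with `alpha`, `sigma2`, `z0`.
#' @export
fit_ou <- function(x, tree, alpha_bounds = c(0, 1000)) {
  m <- match_tip_data(x, tree)
  td <- tip_depth_distance(m$tree)
  negll <- function(a) -gls_profile(m$x, ou_v0(td, a))$logL
  lo <- max(alpha_bounds[1], 1e-8)
  hi <- alpha_bounds[2]
  grid <- exp(seq(log(lo), log(hi), length.out = 30L))
  vals <- vapply(grid, function(a) {
    v <- tryCatch(negll(a), error = function(e) Inf)
    if (is.finite(v)) v else Inf
  }, numeric(1))
  best <- which.min(vals)
  bl <- grid[max(1L, best - 1L)]
  bu <- grid[min(length(grid), best + 1L)]
  opt <- tryCatch(
    stats::optimize(negll, lower = bl, upper = bu, tol = 1e-8),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective) ||
      opt$objective > vals[best]) {
    if (is.null(opt)) {
      warning("OU optimisation failed; reporting best grid point",
              call. = FALSE)
    }
    a_hat <- grid[best]
  } else {
    a_hat <- opt$minimum
  }
  g <- gls_profile(m$x, ou_v0(td, a_hat))
  new_evo_fit("OU", g$logL, 3L, length(m$x),
              list(alpha = a_hat, sigma2 = g$s2, z0 = g$z0))
}

#' Small-sample corrected AIC
#'
#' AICc = -2 logL + 2k + 2k(k+1)/(n-k-1).
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (tips with data); must exceed k + 1.
#' @return The AICc score.
#' @export
aicc <- function(logL, k, n) {
  stopifnot_scalar(logL, "logL")
  if (n <= k + 1) stop("AICc requires n > k + 1", call. = FALSE)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc scores
#'
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2), with Delta relative
#' to the best (minimum) score. Invariant to adding a constant to all
#' scores.
#'
#' @param aicc_values Numeric vector of AICc scores (>= 2).
#' @return Weights summing to 1, same names as input.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 2L) stop("need >= 2 AICc values", call. = FALSE)
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Select the best-fitting evolutionary model
#'
#' Minimum AICc wins; exact ties go to the model with fewer parameters.
#'
#' @param fits List of `evo_fit` objects (one per candidate model).
#' @return The `model` label of the winning fit.
#' @export
select_model <- function(fits) {
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  labs <- vapply(fits, function(f) f$model, character(1))
  ord <- order(round(aiccs, 10), ks)
  labs[ord[1]]
}

#' Compare BM, OU and white-noise fits for one variable
#'
#' @inheritParams fit_ou
#' @return A data frame with one row per model: `model`, `logL`, `k`, `n`,
#'   `aicc`, `akaike_weight`, parameter estimates and a `best` flag.
#' @examples
#' tr <- simulate_tree(20, seed = 1)
#' x <- simulate_bm_traits(tr, matrix(1), seed = 2)[, 1]
#' compare_evo_models(x, tr)
#' @export
compare_evo_models <- function(x, tree, alpha_bounds = c(0, 1000)) {
  m <- match_tip_data(x, tree)
  fits <- list(fit_bm(m$x, m$tree), fit_ou(m$x, m$tree, alpha_bounds),
               fit_wn(m$x))
  w <- akaike_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  best <- select_model(fits)
  out <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(model = f$model, logL = f$logL, k = f$k, n = f$n,
               aicc = f$aicc, akaike_weight = w[i],
               sigma2 = f$params$sigma2,
               z0 = if (!is.null(f$params$z0)) f$params$z0 else
                 f$params$mean,
               alpha = if (!is.null(f$params$alpha)) f$params$alpha else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$best <- out$model == best
  out
}
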