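# Sufficient statistics for the bivariate Brownian-motion likelihood on a
# fixed tree. For X (n x 2) and phylogenetic covariance C, every likelihood
# evaluation needs only a = 1'C^-1 1, b = X'C^-1 1, M = X'C^-1 X and
# log|C|, so MCMC iterations cost O(1) after this O(n^2) precomputation.
pair_suffstats <- function(x_pair, tree) {
  x_pair <- as.matrix(x_pair)
  if (ncol(x_pair) != 2L) stop("'x_pair' must have two columns",
                               call. = FALSE)
  if (is.null(rownames(x_pair))) {
    if (nrow(x_pair) != length(tree$tip.label)) {
      stop("'x_pair' must be named by taxa or have one row per tip",
           call. = FALSE)
    }
    rownames(x_pair) <- tree$tip.label
  }
  keep <- rownames(x_pair)[stats::complete.cases(x_pair)]
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) < 3L) stop("fewer than 3 tips with complete pairs",
                              call. = FALSE)
  if (length(keep) < length(tree$tip.label)) {
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, keep))
  }
  X <- x_pair[tree$tip.label, , drop = FALSE]
  C <- phylo_vcv(tree)
  L <- tryCatch(chol(C), error = function(e) {
    stop("singular phylogenetic covariance", call. = FALSE)
  })
  iC1 <- backsolve(L, forwardsolve(t(L), rep(1, nrow(C))))
  iCX <- backsolve(L, forwardsolve(t(L), X))
  list(n = nrow(X), X = X,
       a = sum(iC1), b = drop(crossprod(X, iC1)), M = crossprod(X, iCX),
       logdetC = 2 * sum(log(diag(L))),
       col_means = colMeans(X), col_sds = apply(X, 2, stats::sd))
}

# log-likelihood from sufficient statistics given R = [[s1,c],[c,s2]]
# (variances s1, s2, covariance c) and root state z0 (length 2)
pair_loglik_ss <- function(ss, s1, s2, rho, z0) {
  cv <- rho * sqrt(s1 * s2)
  detR <- s1 * s2 - cv * cv
  if (detR <= 0) return(-Inf)
  Q11 <- ss$M[1, 1] - 2 * ss$b[1] * z0[1] + ss$a * z0[1]^2
  Q22 <- ss$M[2, 2] - 2 * ss$b[2] * z0[2] + ss$a * z0[2]^2
  Q12 <- ss$M[1, 2] - ss$b[1] * z0[2] - ss$b[2] * z0[1] +
    ss$a * z0[1] * z0[2]
  tr <- (s2 * Q11 + s1 * Q22 - 2 * cv * Q12) / detR
  unname(-ss$n * log(2 * pi) - ss$logdetC - ss$n / 2 * log(detR) - tr / 2)
}

#' Bivariate Brownian-motion log-likelihood
#'
#' Log density of tip values for two traits evolving by correlated Brownian
#' motion: the matrix normal with row covariance `C(tree)`, column
#' covariance `R` (2 x 2 evolutionary rate matrix) and mean `z0` (root
#' state) in each column.
#'
#' @param x_pair Numeric matrix (n tips x 2), rownames = taxa (or rows in
#'   tip order).
#' @param tree A `phylo` object.
#' @param R 2 x 2 positive-definite trait covariance.
#' @param z0 Root state, length 2 (recycled if length 1).
#' @return The log-likelihood (scalar).
#' @export
bivariate_bm_loglik <- function(x_pair, tree, R, z0 = c(0, 0)) {
  R <- as.matrix(R)
  if (!isTRUE(all.equal(R, t(R))) || R[1, 1] <= 0 || R[2, 2] <= 0 ||
      det(R) <= 0) {
    stop("'R' must be symmetric positive-definite", call. = FALSE)
  }
  z0 <- rep_len(z0, 2L)
  ss <- pair_suffstats(x_pair, tree)
  rho <- R[1, 2] / sqrt(R[1, 1] * R[2, 2])
  pair_loglik_ss(ss, R[1, 1], R[2, 2], rho, z0)
}
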