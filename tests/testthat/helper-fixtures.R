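# Small fixed trees used across tests
tree_two <- function() ape::read.tree(text = "(A:1,B:1);")
tree_three <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n, depth = 1) {
  phy <- ape::stree(n, type = "star")
  phy$edge.length <- rep(depth, nrow(phy$edge))
  phy$tip.label <- paste0("s", seq_len(n))
  phy
}

# 2x2 covariance from variances and correlation
rho_R <- function(rho, s1 = 1, s2 = 1) {
  matrix(c(s1, rho * sqrt(s1 * s2), rho * sqrt(s1 * s2), s2), 2, 2)
}

# Conjugate toy for the stepping-stone engine: iid y ~ N(mu, sigma^2) with
# known sigma and prior mu ~ N(mu0, tau0^2). The tempered posterior is
# normal, so `step` is an exact Gibbs draw; the marginal likelihood is the
# closed-form multivariate normal density of y.
conjugate_toy <- function(y, sigma, mu0, tau0) {
  n <- length(y)
  list(
    log_lik = function(th) sum(stats::dnorm(y, th, sigma, log = TRUE)),
    log_prior = function(th) stats::dnorm(th, mu0, tau0, log = TRUE),
    r_prior = function() stats::rnorm(1, mu0, tau0),
    step = function(state, beta, scales) {
      prec <- 1 / tau0^2 + beta * n / sigma^2
      m <- (mu0 / tau0^2 + beta * sum(y) / sigma^2) / prec
      th <- stats::rnorm(1, m, sqrt(1 / prec))
      list(theta = th, ll = sum(stats::dnorm(y, th, sigma, log = TRUE)),
           lp = stats::dnorm(th, mu0, tau0, log = TRUE), acc = 1L)
    })
}

conjugate_toy_evidence <- function(y, sigma, mu0, tau0) {
  n <- length(y)
  V <- diag(sigma^2, n) + tau0^2
  r <- y - mu0
  as.numeric(-n / 2 * log(2 * pi) - 0.5 * determinant(V)$modulus -
               0.5 * (r %*% solve(V, r)))
}

# Dense-matrix oracle for the bivariate BM log density: explicit 2n x 2n
# Kronecker covariance, independent of the sufficient-statistic route.
dense_pair_loglik <- function(X, tree, R, z0) {
  C <- ape::vcv.phylo(tree)[rownames(X), rownames(X)]
  V <- kronecker(R, C)
  n <- nrow(X)
  xv <- as.vector(X) - rep(z0, each = n)
  as.numeric(-n * log(2 * pi) - 0.5 * determinant(V)$modulus -
               0.5 * (xv %*% solve(V, xv)))
}

# Brute-force phylogenetic covariance by path enumeration: shared branch
# length of each tip pair summed edge by edge.
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  plen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path <- function(tip) {
    nodes <- integer(0)
    cur <- tip
    while (cur != root) {
      nodes <- c(nodes, cur)
      cur <- parent[cur]
    }
    nodes
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- sum(plen[intersect(paths[[i]], paths[[j]])])
    }
  }
  C
}
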