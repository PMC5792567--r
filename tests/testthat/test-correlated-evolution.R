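test_that("bivariate BM likelihood factorises, is symmetric and matches a dense oracle", {
  t5 <- simulate_tree(5, 1, seed = 9)
  # rho = 0: sum of the two univariate BM log-likelihoods
  R0 <- diag(c(1.3, 0.7))
  X <- simulate_bm_traits(t5, R0, c(0.5, -0.2), seed = 2)
  C <- phylo_vcv(t5)
  uni <- function(x, s2, mu) {
    n <- length(x)
    -n / 2 * log(2 * pi) - 0.5 * determinant(s2 * C)$modulus -
      0.5 * drop((x - mu) %*% solve(s2 * C, x - mu))
  }
  expect_equal(bivariate_bm_loglik(X, t5, R0, c(0.5, -0.2)),
               as.numeric(uni(X[, 1], 1.3, 0.5) + uni(X[, 2], 0.7, -0.2)),
               tolerance = 1e-10)
  # trait-swap symmetry
  R <- rho_R(0.4, 2, 0.5)
  expect_equal(bivariate_bm_loglik(X, t5, R, c(1, 2)),
               bivariate_bm_loglik(X[, 2:1], t5, R[2:1, 2:1], c(2, 1)),
               tolerance = 1e-10)
  # dense 2n x 2n Kronecker oracle
  set.seed(3)
  for (r in 1:20) {
    Rr <- rho_R(stats::runif(1, -0.9, 0.9), exp(stats::rnorm(1)),
                exp(stats::rnorm(1)))
    z0 <- stats::rnorm(2)
    Xr <- simulate_bm_traits(t5, Rr, z0)
    expect_equal(bivariate_bm_loglik(Xr, t5, Rr, z0),
                 dense_pair_loglik(Xr, t5, Rr, z0), tolerance = 1e-8)
  }
  expect_error(bivariate_bm_loglik(X, t5, matrix(c(1, 2, 2, 1), 2), c(0, 0)),
               "positive-definite")
})

test_that("the pair sampler respects model constraints and seeds", {
  tr <- simulate_tree(50, 1, seed = 12)
  X <- simulate_bm_traits(tr, rho_R(0.5), seed = 13)
  cfg <- ss_config(n_stones = 5, iterations_per_stone = 200,
                   mcmc_burnin = 50, seed = 21)
  ind <- run_mcmc(X, tr, "independent", cfg)
  expect_true(all(ind$rho == 0))
  a <- run_mcmc(X, tr, "dependent", cfg)
  b <- run_mcmc(X, tr, "dependent", cfg)
  expect_identical(a, b)
  expect_true(all(attr(a, "acceptance") >= 0.05 &
                    attr(a, "acceptance") <= 0.8))
})

test_that("the posterior correlation tracks the generating value", {
  tr <- simulate_tree(100, 1, seed = 21)
  X <- simulate_bm_traits(tr, rho_R(0.7), seed = 22)
  post <- run_mcmc(X, tr, "dependent",
                   ss_config(mcmc_burnin = 200, seed = 5),
                   n_iterations = 1500)
  expect_lt(abs(mean(post$rho) - 0.7), 0.15)
  # and agrees with the ML correlation of phylogenetically whitened data
  L <- chol(phylo_vcv(tr))
  W <- forwardsolve(t(L), cbind(1, X))  # whiten: cov(L^-T y) = I
  res <- stats::lm.fit(W[, 1, drop = FALSE], W[, 2:3])$residuals
  expect_lt(abs(mean(post$rho) - stats::cor(res[, 1], res[, 2])), 0.1)
})

test_that("a flat likelihood yields zero evidence in the SS engine", {
  flat <- list(
    log_lik = function(th) 0,
    log_prior = function(th) stats::dnorm(th, log = TRUE),
    r_prior = function() stats::rnorm(1),
    step = function(state, beta, scales) {
      th <- stats::rnorm(1)
      list(theta = th, ll = 0, lp = stats::dnorm(th, log = TRUE), acc = 1L)
    })
  ev <- power_posterior_evidence(flat, ss_config(10, 100, seed = 1))
  expect_equal(as.numeric(ev), 0)
})

test_that("stepping stone is invariant to trait order", {
  tr <- simulate_tree(50, 1, seed = 31)
  X <- simulate_bm_traits(tr, rho_R(0.6), seed = 32)
  cfg <- ss_config(n_stones = 40, iterations_per_stone = 600,
                   mcmc_burnin = 150, seed = 7)
  e1 <- stepping_stone(X, tr, "dependent", cfg)
  cfg$seed <- 8
  e2 <- stepping_stone(X[, 2:1], tr, "dependent", cfg)
  expect_lt(abs(as.numeric(e1) - as.numeric(e2)), 0.3)
})

test_that("log Bayes factors, support tiers and thresholds are exact", {
  expect_equal(log_bayes_factor(-100, -105), 10)
  expect_equal(log_bayes_factor(-3.2, -3.2), 0)
  expect_equal(log_bayes_factor(-105, -100), -log_bayes_factor(-100, -105))
  expect_equal(as.character(classify_support(c(11, 6, 3, 0, -4))),
               c("strong", "moderate", "weak", "none", "none"))
  expect_equal(mc_threshold(110), 5 + log(110))
  expect_equal(round(mc_threshold(110), 2), 9.70)
  expect_equal(mc_threshold(1), 5)
  expect_equal(mc_threshold(exp(5)), 10)
  expect_error(mc_threshold(0), ">= 1")
})

test_that("test_pair assembles a coherent pair result", {
  tr <- simulate_tree(60, 1, seed = 41)
  X <- simulate_bm_traits(tr, rho_R(0.8), seed = 42)
  colnames(X) <- c("height", "mat")
  cfg <- ss_config(n_stones = 15, iterations_per_stone = 250,
                   mcmc_burnin = 80, seed = 3)
  res <- test_pair(X, tr, cfg, n_comparisons = 110)
  expect_equal(res$var_a, "height")
  expect_equal(res$var_b, "mat")
  expect_equal(res$logBF, 2 * (res$SS_dep - res$SS_indep))
  expect_equal(res$support,
               as.character(classify_support(res$logBF)))
  expect_identical(res$passes_mc_threshold, res$logBF > mc_threshold(110))
  expect_gt(res$rho_estimate, 0.4)
})
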