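test_that("Yule simulation produces valid trees of the requested size", {
  tr <- simulate_tree(2, 1, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 2L)
  expect_identical(tr$Nnode, 1L)

  tr58 <- simulate_tree(58, 1, seed = 7)
  expect_length(tr58$tip.label, 58L)
  expect_identical(tr58$Nnode, 57L)  # fully bifurcating
  expect_true(all(tr58$edge.length >= 0))
  expect_false(anyDuplicated(tr58$tip.label) > 0)

  expect_error(simulate_tree(1), "n_taxa")
  # reproducible under seed
  expect_equal(ape::write.tree(simulate_tree(10, 1, seed = 3)),
               ape::write.tree(simulate_tree(10, 1, seed = 3)))
})

test_that("tip depths match the analytic Yule expectation", {
  # forward Yule stopped at n tips + final Exp(n lambda) segment:
  # E[depth] = sum_{k=2}^{n} 1/(k lambda)
  n <- 8
  depths <- vapply(1:1000, function(r) {
    tr <- simulate_tree(n, 1, seed = 5000 + r)
    max(ape::node.depth.edgelength(tr)[seq_len(n)])
  }, numeric(1))
  expected <- sum(1 / (2:n))
  expect_lt(abs(mean(depths) - expected),
            3 * stats::sd(depths) / sqrt(length(depths)) + 0.02)
})

test_that("tree perturbation preserves taxa and branch-length positivity", {
  tr <- simulate_tree(12, 1, seed = 2)
  expect_equal(ape::write.tree(perturb_tree(tr, 0, 0, seed = 1)),
               ape::write.tree(tr))
  p1 <- perturb_tree(tr, 1, 0, seed = 4)
  expect_setequal(p1$tip.label, tr$tip.label)
  expect_true(phangorn::RF.dist(p1, tr) %in% c(0, 2))
  pj <- perturb_tree(tr, 0, 0.1, seed = 5)
  expect_equal(phangorn::RF.dist(pj, tr), 0)
  expect_true(all(pj$edge.length > 0))
  bs <- bootstrap_trees(tr, n_trees = 5, seed = 9)
  expect_length(bs, 5L)
  expect_setequal(bs[[3]]$tip.label, tr$tip.label)
})

test_that("Brownian simulation matches its matrix-normal distribution", {
  # degenerate tree: every tip equals the root state
  z <- star_tree(4, depth = 0)
  X <- simulate_bm_traits(z, rho_R(0.5), root_state = c(2, -1), seed = 1)
  expect_true(all(X[, 1] == 2) && all(X[, 2] == -1))

  # star tree of depth t: tip variance = sigma^2 t
  st <- star_tree(10, depth = 2)
  sims <- vapply(1:2000, function(r) {
    simulate_bm_traits(st, matrix(1.5), seed = 100 + r)[, 1]
  }, numeric(10))
  expect_lt(abs(stats::var(as.vector(sims)) - 3), 0.15)

  # 4-taxon tree: empirical mean and covariance of tip vectors agree with
  # z0 and R (x) C
  tr <- simulate_tree(4, 1, seed = 11)
  C <- phylo_vcv(tr)
  R <- rho_R(0.6, 1.2, 0.8)
  sims <- vapply(1:4000, function(r) {
    as.vector(simulate_bm_traits(tr, R, c(1, 2), seed = 4000 + r))
  }, numeric(8))
  emp_mean <- rowMeans(sims)
  expect_lt(max(abs(emp_mean - rep(c(1, 2), each = 4))), 0.1)
  emp_cov <- stats::cov(t(sims))
  expect_lt(max(abs(emp_cov - kronecker(R, C))), 0.25)

  expect_error(simulate_bm_traits(tr, matrix(c(1, 2, 2, 1), 2, 2)),
               "positive-definite")
})

test_that("simulated BM pairs recover the generating contrast correlation", {
  cors <- vapply(1:30, function(r) {
    tr <- simulate_tree(100, 1, seed = 600 + r)
    X <- simulate_bm_traits(tr, rho_R(0.8), seed = 700 + r)
    stats::cor(ape::pic(X[, 1], tr), ape::pic(X[, 2], tr))
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.8), 0.05)
})

test_that("observation noise layers behave as specified", {
  mu <- matrix(c(3, -1), 1, 2, dimnames = list("sp1", c("a", "b")))
  noiseless <- simulate_observations(mu, 3, 4, site_sd = 0, resid_sd = 0,
                                     seed = 1)
  expect_true(all(noiseless$a == 3) && all(noiseless$b == -1))
  expect_equal(nrow(noiseless), 12L)

  # residual sd recovered from a single site
  big <- simulate_observations(mu[, 1, drop = FALSE], 1, 10000,
                               site_sd = 0, resid_sd = 1, seed = 2)
  expect_lt(abs(stats::sd(big$a) - 1), 0.03)

  # dominant site effect: within-site spread << between-site spread
  two <- simulate_observations(mu[, 1, drop = FALSE], 2, 50,
                               site_sd = 10, resid_sd = 0.1, seed = 3)
  within <- tapply(two$a, two$site, stats::var)
  expect_lt(max(within), stats::var(tapply(two$a, two$site, mean)))

  # additive independent layers: total variance ~ site_sd^2 + resid_sd^2
  many <- simulate_observations(mu[, 1, drop = FALSE], 400, 4,
                                site_sd = 2, resid_sd = 0.5, seed = 4)
  expect_lt(abs(stats::var(many$a) - 4.25), 0.45)
})

test_that("occupancy surfaces are unimodal around the niche centre", {
  one <- simulate_occupancy(c(mat = 10), spread = 1, n_cells = 1, seed = 1)
  expect_equal(one$probability, 1)
  surf <- simulate_occupancy(c(mat = 16), spread = 2, n_cells = 5000,
                             seed = 5)
  expect_true(all(surf$probability >= 0 & surf$probability <= 1))
  expect_lt(abs(stats::weighted.mean(surf$mat, surf$probability) - 16),
            0.15)
  expect_error(simulate_occupancy(c(mat = 1), spread = 0, n_cells = 5),
               "spread")
})

test_that("the study generator wires all pieces together", {
  st <- simulate_study(n_taxa = 8, n_boot = 3, n_cells = 50, seed = 42)
  expect_length(st$tree$tip.label, 8L)
  expect_length(st$boot_trees, 3L)
  expect_setequal(rownames(st$species_means), st$tree$tip.label)
  expect_setequal(unique(st$observations$species), st$tree$tip.label)
  expect_named(st$occupancy, "mat")
  expect_length(st$occupancy$mat, 8L)
  # same seed, same study
  st2 <- simulate_study(n_taxa = 8, n_boot = 3, n_cells = 50, seed = 42)
  expect_identical(st$species_means, st2$species_means)
})
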