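test_that("derived traits follow their defining formulas", {
  raw <- data.frame(canopy_d1 = 2, canopy_d2 = 4, fresh_mass = 3,
                    dry_mass = 1, area = 2, length = 10, width = 2)
  d <- derive_traits(raw)
  expect_equal(d$canopy, 2 * pi)
  expect_equal(d$fwc, 2.0)
  expect_equal(d$lwr, 5.0)
  expect_equal(d$lma, 0.5)

  bad <- rbind(raw, within(raw, dry_mass <- 0))
  expect_message(db <- derive_traits(bad), "skipped")
  expect_identical(attr(db, "skipped"), 2L)
  expect_true(is.na(db$fwc[2]))
  expect_false(anyNA(db$fwc[1]))
})

test_that("log transform applies to every trait except the carbon isotope", {
  expect_equal(transform_trait(exp(1), "lma"), 1.0)
  expect_equal(transform_trait(-26.1, "d13C"), -26.1)
  expect_equal(transform_trait(1.0, "height"), 0.0)
  expect_error(transform_trait(c(2, -1), "height"), "nonpositive")
})

test_that("HPD intervals are shortest contiguous intervals", {
  expect_equal(unname(hpd_interval(rep(1, 4), 0.95)), c(1, 1))
  h <- hpd_interval(1:100, 0.95)
  expect_equal(unname(h[2] - h[1]), 94)  # exactly 95 consecutive values
  set.seed(1)
  hn <- hpd_interval(stats::rnorm(1e5), 0.95)
  expect_lt(max(abs(hn - stats::qnorm(c(0.025, 0.975)))), 0.05)
  # never wider than the equal-tailed interval at the same mass
  for (r in 1:20) {
    set.seed(r)
    x <- stats::rgamma(2000, shape = 2)
    h <- hpd_interval(x, 0.9)
    q <- stats::quantile(x, c(0.05, 0.95))
    expect_lte(h[2] - h[1], q[2] - q[1] + 1e-12)
  }
})

test_that("draw subsampling is uniform, seeded and error-checked", {
  x <- stats::rnorm(10000)
  expect_setequal(subsample_draws(x, length(x), seed = 1), x)
  expect_identical(subsample_draws(x, 100, seed = 5),
                   subsample_draws(x, 100, seed = 5))
  expect_error(subsample_draws(x, 10001), "exceeds")
  d <- subsample_draws(x, 100, seed = 2)
  expect_lt(abs(mean(d) - mean(x)), 3 * stats::sd(x) / sqrt(100))
})

test_that("species-trait posterior concentrates on the truth", {
  set.seed(1)
  y <- stats::rnorm(4000, 5, 0.3)
  s <- rep(1:10, each = 400)
  f <- fit_species_trait(y, s, trait_model_config(2, 1500, seed = 3))
  expect_lt(abs(f$posterior_mean - 5), 0.03)
  expect_lt(f$hpd_low, f$posterior_mean)
  expect_gt(f$hpd_high, f$posterior_mean)
  expect_length(f$draws, 100L)
})

test_that("a single observation shrinks between prior mean and datum", {
  f <- fit_species_trait(2, "siteA",
                         trait_model_config(1, 4000, seed = 2),
                         prior_mean = 0, prior_sd = 1, sigma_fixed = 1)
  expect_gt(f$posterior_mean, 0.8)
  expect_lt(f$posterior_mean, 1.2)  # equal precision: midpoint 1
})

test_that("the conjugate no-random-effect case matches the closed form", {
  set.seed(4)
  y <- stats::rnorm(50, 1, 1)
  f <- fit_species_trait(y, rep(1, 50),
                         trait_model_config(1, 20000, seed = 4),
                         prior_mean = 0, prior_sd = 2, sigma_fixed = 1)
  prec <- 1 / 4 + 50
  m <- sum(y) / prec
  ks <- stats::ks.test(f$samples, "pnorm", m, sqrt(1 / prec))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("zero-variance data collapse to a point with a warning", {
  expect_warning(f <- fit_species_trait(rep(3, 10), rep(1, 10),
                                        trait_model_config(1, 200)),
                 "zero variance")
  expect_equal(f$posterior_mean, 3)
  expect_equal(c(f$hpd_low, f$hpd_high), c(3, 3))
  expect_error(fit_species_trait(numeric(0)), "no observations")
})

test_that("estimated species means track true means with slope ~ 1", {
  set.seed(10)
  n_sp <- 50
  truth <- stats::rnorm(n_sp, 0, 2)
  cfg <- trait_model_config(1, 1200)
  est <- vapply(seq_len(n_sp), function(i) {
    u <- stats::rnorm(5, 0, 0.5)
    site <- rep(1:5, each = 8)
    y <- truth[i] + u[site] + stats::rnorm(40, 0, 0.3)
    cfg$seed <- 300 + i
    fit_species_trait(y, site, cfg)$posterior_mean
  }, numeric(1))
  slope <- stats::coef(stats::lm(est ~ truth))[2]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("fit_all_species produces tidy summary and draw tables", {
  mu <- matrix(c(10, 20, 2, 3), 2, 2,
               dimnames = list(c("sp1", "sp2"), c("height", "d13C")))
  obs <- simulate_observations(mu, 2, 6, site_sd = 0.1, resid_sd = 0.1,
                               seed = 1)
  res <- fit_all_species(obs, config = trait_model_config(1, 600, seed = 2),
                         log_transform = TRUE)
  expect_equal(nrow(res$summary), 4L)
  expect_equal(nrow(res$draws), 4L * 100L)
  # height was log-transformed, d13C not
  h1 <- res$summary[res$summary$species == "sp1" &
                      res$summary$variable == "height", ]
  expect_lt(abs(h1$posterior_mean - log(10)), 0.2)
  d2 <- res$summary[res$summary$species == "sp2" &
                      res$summary$variable == "d13C", ]
  expect_lt(abs(d2$posterior_mean - 3), 0.2)
})
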