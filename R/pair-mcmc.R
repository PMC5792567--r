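#' Stepping-stone / MCMC configuration
#'
#' Defaults mirror the published analysis: 100 stones with 1,000 iterations
#' per stone, powers placed at quantiles of a Beta(`beta_shape`, 1)
#' distribution (so stones concentrate near the prior, where the integrand
#' changes fastest).
#'
#' @param n_stones Number of stones (power-posterior temperatures).
#' @param iterations_per_stone Recorded iterations per stone.
#' @param beta_shape Shape of the Beta(shape, 1) power schedule.
#' @param mcmc_burnin Discarded iterations when moving to a new stone (and
#'   warmup fraction guidance for [run_mcmc()]).
#' @param proposal_scales Base random-walk scales: `log_sigma` for the log
#'   rate parameters and `rho_z` for the Fisher-z correlation. Scales are
#'   shrunk deterministically as the tempering power and data size grow.
#' @param seed Optional integer seed.
#' @return A list of class `ss_config`.
#' @export
ss_config <- function(n_stones = 100, iterations_per_stone = 1000,
                      beta_shape = 0.4, mcmc_burnin = 100,
                      proposal_scales = c(log_sigma = 2.4, rho_z = 2.4),
                      seed = NULL) {
  if (n_stones < 1) stop("'n_stones' must be >= 1", call. = FALSE)
  structure(list(n_stones = n_stones,
                 iterations_per_stone = iterations_per_stone,
                 beta_shape = beta_shape, mcmc_burnin = mcmc_burnin,
                 proposal_scales = proposal_scales, seed = seed),
            class = "ss_config")
}

# Bivariate-BM model object for the power-posterior machinery.
# Parameters theta = (l1, l2, z, z0_1, z0_2) with l_j = log sigma_j^2 and
# z = atanh(rho); the independence model fixes z = 0.
# Priors (proper, required for marginal likelihoods):
#   l_j ~ Normal(log of the GLS Brownian rate estimate, sd 2)
#   rho ~ Uniform(-1, 1)  [density (1 - rho^2)/2 on the z scale]
#   z0_j ~ Normal(grand mean of trait j, (10 x data sd)^2)
bm_pair_model <- function(x_pair, tree, correlation_free = TRUE) {
  ss <- pair_suffstats(x_pair, tree)
  # GLS Brownian rate per trait centres the log-rate prior
  s2_gls <- pmax(c(ss$M[1, 1] - ss$b[1]^2 / ss$a,
                   ss$M[2, 2] - ss$b[2]^2 / ss$a) / ss$n, 1e-12)
  prior <- list(l_mean = log(s2_gls), l_sd = 2,
                z0_mean = ss$col_means, z0_sd = 10 * pmax(ss$col_sds, 1e-8))

  unpack <- function(theta) {
    list(s1 = exp(theta[1]), s2 = exp(theta[2]), rho = tanh(theta[3]),
         z0 = theta[4:5])
  }
  log_lik <- function(theta) {
    p <- unpack(theta)
    pair_loglik_ss(ss, p$s1, p$s2, p$rho, p$z0)
  }
  log_prior <- function(theta) {
    rho <- tanh(theta[3])
    lp <- stats::dnorm(theta[1], prior$l_mean[1], prior$l_sd, log = TRUE) +
      stats::dnorm(theta[2], prior$l_mean[2], prior$l_sd, log = TRUE) +
      sum(stats::dnorm(theta[4:5], prior$z0_mean, prior$z0_sd, log = TRUE))
    if (correlation_free) lp <- lp + log((1 - rho^2) / 2)
    lp
  }
  r_prior <- function() {
    z <- if (correlation_free) atanh(stats::runif(1, -1, 1)) else 0
    c(stats::rnorm(2, prior$l_mean, prior$l_sd), z,
      stats::rnorm(2, prior$z0_mean, prior$z0_sd))
  }
  # one Metropolis-within-Gibbs sweep at tempering power beta:
  # Gibbs update of z0 (bivariate normal conditional), random-walk MH on
  # l1, l2 and (if free) z, with scales shrunk as beta * n grows
  step <- function(state, beta, scales) {
    theta <- state$theta
    p <- unpack(theta)
    # exact Gibbs draw of z0 | rest from tempered likelihood x prior
    cv <- p$rho * sqrt(p$s1 * p$s2)
    detR <- p$s1 * p$s2 - cv * cv
    iR <- matrix(c(p$s2, -cv, -cv, p$s1), 2, 2) / detR
    P <- beta * ss$a * iR + diag(1 / prior$z0_sd^2)
    h <- beta * iR %*% ss$b + prior$z0_mean / prior$z0_sd^2
    Lp <- chol(P)
    mu <- backsolve(Lp, forwardsolve(t(Lp), h))
    theta[4:5] <- drop(mu + backsolve(Lp, stats::rnorm(2)))
    ll <- log_lik(theta)
    lp <- log_prior(theta)
    acc <- integer(0)
    idx <- if (correlation_free) 1:3 else 1:2
    sc <- c(scales[["log_sigma"]] / sqrt(beta * ss$n / 2 + 1 / 4),
            scales[["log_sigma"]] / sqrt(beta * ss$n / 2 + 1 / 4),
            scales[["rho_z"]] / sqrt(beta * ss$n + 1))
    for (j in idx) {
      cand <- theta
      cand[j] <- cand[j] + stats::rnorm(1, 0, sc[j])
      ll_c <- log_lik(cand)
      lp_c <- log_prior(cand)
      if (is.finite(ll_c + lp_c) &&
          log(stats::runif(1)) < beta * (ll_c - ll) + lp_c - lp) {
        theta <- cand
        ll <- ll_c
        lp <- lp_c
        acc <- c(acc, 1L)
      } else {
        acc <- c(acc, 0L)
      }
    }
    list(theta = theta, ll = ll, lp = lp, acc = acc)
  }
  list(log_lik = log_lik, log_prior = log_prior, r_prior = r_prior,
       step = step, unpack = unpack, suffstats = ss, prior = prior,
       correlation_free = correlation_free)
}

#' Posterior sampling for a bivariate Brownian-motion pair
#'
#' Metropolis-within-Gibbs sampling of (sigma1^2, sigma2^2, rho, z0) under
#' the dependent model (`rho` free, proposed on the Fisher-z scale) or the
#' independence model (`rho` fixed at zero). Rates are proposed on the log
#' scale; the root state is updated by an exact Gibbs draw.
#'
#' @param x_pair Numeric matrix (n x 2) with taxon rownames.
#' @param tree A `phylo` object.
#' @param model `"dependent"` or `"independent"`.
#' @param config An [ss_config()]; `iterations_per_stone` is the number of
#'   recorded iterations and `mcmc_burnin` the warmup.
#' @param n_iterations Recorded iterations (default
#'   `config$iterations_per_stone`).
#' @return Data frame of posterior samples: `sigma1_sq`, `sigma2_sq`,
#'   `rho`, `z0_1`, `z0_2`, `loglik`; acceptance rates in the
#'   `acceptance` attribute. A warning is raised if any block's acceptance
#'   rate falls outside [0.05, 0.8].
#' @export
run_mcmc <- function(x_pair, tree, model = c("dependent", "independent"),
                     config = ss_config(), n_iterations = NULL) {
  model <- match.arg(model)
  m <- bm_pair_model(x_pair, tree, correlation_free = model == "dependent")
  n_it <- if (is.null(n_iterations)) config$iterations_per_stone else
    n_iterations
  with_seed(config$seed, {
    state <- init_state(m)
    out <- matrix(NA_real_, n_it, 6)
    acc <- 0
    npar <- if (m$correlation_free) 3L else 2L
    acc_n <- 0L
    for (it in seq_len(config$mcmc_burnin + n_it)) {
      res <- m$step(state, 1, config$proposal_scales)
      state <- list(theta = res$theta, ll = res$ll)
      if (it > config$mcmc_burnin) {
        acc <- acc + res$acc
        acc_n <- acc_n + 1L
        p <- m$unpack(res$theta)
        out[it - config$mcmc_burnin, ] <- c(p$s1, p$s2, p$rho, p$z0,
                                            res$ll)
      }
    }
    rate <- acc / acc_n
    if (any(rate < 0.05 | rate > 0.8)) {
      warning(sprintf("MCMC acceptance rate outside [0.05, 0.8]: %s",
                      paste(sprintf("%.2f", rate), collapse = ", ")),
              call. = FALSE)
    }
    out <- as.data.frame(out)
    names(out) <- c("sigma1_sq", "sigma2_sq", "rho", "z0_1", "z0_2",
                    "loglik")
    attr(out, "acceptance") <- rate
    out
  })
}

init_state <- function(m) {
  # start at the GLS point: log rates at their prior centres, rho at the
  # GLS cross-trait correlation, z0 at the GLS means
  ss <- m$suffstats
  z_gls <- ss$b / ss$a
  Q12 <- ss$M[1, 2] - ss$b[1] * z_gls[2] - ss$b[2] * z_gls[1] +
    ss$a * z_gls[1] * z_gls[2]
  s2 <- exp(m$prior$l_mean)
  r0 <- if (m$correlation_free) {
    max(min(Q12 / ss$n / sqrt(prod(s2)), 0.99), -0.99)
  } else 0
  theta <- c(m$prior$l_mean, atanh(r0), z_gls)
  list(theta = theta, ll = m$log_lik(theta))
}

#' Stepping-stone estimate of a log marginal likelihood
#'
#' Generic power-posterior engine: given a model object exposing
#' `log_lik(theta)`, `log_prior(theta)`, `r_prior()` and
#' `step(state, beta, scales)` (one MCMC sweep targeting
#' `likelihood^beta x prior`), estimates the log marginal likelihood by
#' stepping-stone sampling. Powers are `beta_k = (k / K)^(1/shape)` for
#' `k = 0 .. K-1` (quantiles of Beta(shape, 1)); the stone at `beta = 0`
#' is sampled iid from the prior, later stones reuse the previous stone's
#' final state as a warm start, moving from prior to posterior.
#'
#' @param model Model object (see [bm_pair_model] interface above); built
#'   internally by [stepping_stone()] for trait pairs.
#' @param config An [ss_config()].
#' @return The estimated log marginal likelihood, with per-stone
#'   contributions in attribute `stones`.
#' @export
power_posterior_evidence <- function(model, config = ss_config()) {
  K <- config$n_stones
  m_it <- config$iterations_per_stone
  betas <- (seq_len(K + 1L) - 1L)^(1 / config$beta_shape) /
    K^(1 / config$beta_shape)  # beta_0 = 0 ... beta_K = 1
  with_seed(config$seed, {
    contrib <- numeric(K)
    state <- NULL
    for (k in seq_len(K)) {
      b_lo <- betas[k]
      b_hi <- betas[k + 1L]
      ll <- numeric(m_it)
      if (b_lo == 0) {
        # prior stone: iid sampling, no MCMC needed
        for (i in seq_len(m_it)) {
          theta <- model$r_prior()
          ll[i] <- model$log_lik(theta)
        }
        theta <- model$r_prior()
        state <- list(theta = theta, ll = model$log_lik(theta))
      } else {
        for (i in seq_len(config$mcmc_burnin)) {
          res <- model$step(state, b_lo, config$proposal_scales)
          state <- list(theta = res$theta, ll = res$ll)
        }
        for (i in seq_len(m_it)) {
          res <- model$step(state, b_lo, config$proposal_scales)
          state <- list(theta = res$theta, ll = res$ll)
          ll[i] <- res$ll
        }
      }
      d <- b_hi - b_lo
      contrib[k] <- log_sum_exp(d * ll) - log(m_it)
    }
    out <- sum(contrib)
    attr(out, "stones") <- contrib
    out
  })
}

#' Stepping-stone marginal likelihood for a trait pair
#'
#' @inheritParams run_mcmc
#' @return Log marginal likelihood (scalar, `stones` attribute with
#'   per-stone contributions).
#' @export
stepping_stone <- function(x_pair, tree,
                           model = c("dependent", "independent"),
                           config = ss_config()) {
  model <- match.arg(model)
  m <- bm_pair_model(x_pair, tree, correlation_free = model == "dependent")
  power_posterior_evidence(m, config)
}

#' Log Bayes factor from two stepping-stone estimates
#'
#' `logBF = 2 * (SS_dep - SS_indep)`.
#'
#' @param ss_dep,ss_indep Log marginal likelihoods of the dependent and
#'   independence models.
#' @return The log Bayes factor.
#' @export
log_bayes_factor <- function(ss_dep, ss_indep) {
  stopifnot_scalar(as.numeric(ss_dep), "ss_dep")
  stopifnot_scalar(as.numeric(ss_indep), "ss_indep")
  2 * (as.numeric(ss_dep) - as.numeric(ss_indep))
}

#' Support tier for a log Bayes factor
#'
#' Weak support above 2, moderate above 5, strong above 10.
#'
#' @param logBF Numeric vector of log Bayes factors.
#' @return Factor with levels `none`, `weak`, `moderate`, `strong`.
#' @export
classify_support <- function(logBF) {
  if (any(!is.finite(logBF))) stop("'logBF' must be finite", call. = FALSE)
  cut(logBF, breaks = c(-Inf, 2, 5, 10, Inf),
      labels = c("none", "weak", "moderate", "strong"), right = TRUE)
}

#' Multiple-comparison threshold for log Bayes factors
#'
#' Raises the moderate-support cutoff by the log of the number of model
#' comparisons: `5 + log(N)`.
#'
#' @param n_comparisons Number of model comparisons performed (>= 1).
#' @return The logBF threshold.
#' @examples
#' mc_threshold(110) # 9.70
#' @export
mc_threshold <- function(n_comparisons) {
  if (n_comparisons < 1) stop("'n_comparisons' must be >= 1", call. = FALSE)
  5 + log(n_comparisons)
}

#' Test correlated evolution for one variable pair
#'
#' Runs the dependent and independence stepping-stone analyses plus a
#' posterior chain for the correlation, and assembles the pair result:
#' posterior-mean correlation, the two log marginal likelihoods, the log
#' Bayes factor, its support tier, and whether it clears the
#' multiple-comparison threshold.
#'
#' @inheritParams run_mcmc
#' @param var_a,var_b Variable labels (default from `x_pair` column names).
#' @param n_comparisons Number of comparisons for [mc_threshold()].
#' @param mc_cutoff Optional explicit logBF cutoff overriding the
#'   `5 + log(N)` formula.
#' @return One-row data frame: `var_a`, `var_b`, `rho_estimate`, `SS_dep`,
#'   `SS_indep`, `logBF`, `support`, `passes_mc_threshold`.
#' @export
test_pair <- function(x_pair, tree, config = ss_config(),
                      var_a = NULL, var_b = NULL, n_comparisons = 1,
                      mc_cutoff = NULL) {
  x_pair <- as.matrix(x_pair)
  if (is.null(var_a)) var_a <- colnames(x_pair)[1]
  if (is.null(var_b)) var_b <- colnames(x_pair)[2]
  if (is.null(var_a) || is.null(var_b)) {
    var_a <- "var_a"
    var_b <- "var_b"
  }
  cfg_dep <- config; cfg_dep$seed <- sub_seed(config$seed, 11L)
  cfg_ind <- config; cfg_ind$seed <- sub_seed(config$seed, 12L)
  cfg_mc <- config; cfg_mc$seed <- sub_seed(config$seed, 13L)
  ss_dep <- stepping_stone(x_pair, tree, "dependent", cfg_dep)
  ss_ind <- stepping_stone(x_pair, tree, "independent", cfg_ind)
  post <- run_mcmc(x_pair, tree, "dependent", cfg_mc)
  bf <- log_bayes_factor(ss_dep, ss_ind)
  cutoff <- if (is.null(mc_cutoff)) mc_threshold(n_comparisons) else
    mc_cutoff
  data.frame(var_a = var_a, var_b = var_b,
             rho_estimate = mean(post$rho),
             SS_dep = as.numeric(ss_dep), SS_indep = as.numeric(ss_ind),
             logBF = bf, support = as.character(classify_support(bf)),
             passes_mc_threshold = bf > cutoff,
             stringsAsFactors = FALSE)
}
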