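#' Derive composite traits from raw field measurements
#'
#' Adds the derived columns used in downstream analyses:
#' * `canopy`  - canopy area from two orthogonal crown diameters by the
#'   ellipse formula, pi * (d1/2) * (d2/2);
#' * `lma`     - leaf mass per area, `dry_mass / area`;
#' * `fwc`     - leaf freshwater content, `(fresh_mass - dry_mass) / dry_mass`;
#' * `lwr`     - leaf length-to-width ratio, `length / width`.
#'
#' Records with a zero or negative divisor (area, dry mass, width) get `NA`
#' for the affected derived trait and are reported in the `skipped`
#' attribute (and via a message).
#'
#' @param raw Data frame with any of the columns `canopy_d1`, `canopy_d2`,
#'   `dry_mass`, `fresh_mass`, `area`, `length`, `width`. Other columns are
#'   passed through.
#' @return `raw` with derived columns appended and an attribute `skipped`
#'   (integer row indices with at least one invalid divisor).
#' @export
derive_traits <- function(raw) {
  out <- raw
  skipped <- integer(0)
  bad <- function(x) !is.na(x) & x <= 0
  if (all(c("canopy_d1", "canopy_d2") %in% names(raw))) {
    out$canopy <- pi * (raw$canopy_d1 / 2) * (raw$canopy_d2 / 2)
  }
  if (all(c("dry_mass", "area") %in% names(raw))) {
    div <- bad(raw$area)
    out$lma <- ifelse(div, NA_real_, raw$dry_mass / raw$area)
    skipped <- c(skipped, which(div))
  }
  if (all(c("fresh_mass", "dry_mass") %in% names(raw))) {
    div <- bad(raw$dry_mass)
    out$fwc <- ifelse(div, NA_real_,
                      (raw$fresh_mass - raw$dry_mass) / raw$dry_mass)
    skipped <- c(skipped, which(div))
  }
  if (all(c("length", "width") %in% names(raw))) {
    div <- bad(raw$width)
    out$lwr <- ifelse(div, NA_real_, raw$length / raw$width)
    skipped <- c(skipped, which(div))
  }
  skipped <- sort(unique(skipped))
  if (length(skipped)) {
    message(length(skipped), " record(s) skipped for nonpositive divisors: ",
            paste(utils::head(skipped, 10), collapse = ", "))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Natural-log transform of a trait, with the carbon-isotope exemption
#'
#' All traits are natural-log transformed before analysis except the leaf
#' carbon isotope ratio (delta13C), which can be negative and passes
#' through unchanged.
#'
#' @param values Numeric vector.
#' @param trait_name Trait label.
#' @param exempt Trait names left untransformed (default `"d13C"`;
#'   `"delta13C"` is also recognised).
#' @return Transformed values.
#' @export
transform_trait <- function(values, trait_name,
                            exempt = c("d13C", "delta13C")) {
  if (trait_name %in% exempt) return(values)
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive value for log-transformed trait '%s' at record(s) %s",
                 trait_name, paste(utils::head(bad, 10), collapse = ", ")),
         call. = FALSE)
  }
  log(values)
}

#' Configuration for the hierarchical species-trait model
#'
#' Defaults mirror the published analysis scale: four chains of 5,000
#' iterations each (half warmup) saving 10,000 posterior samples in total,
#' 95% HPD intervals and 100 random draws per species x trait.
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain (first half is warmup).
#' @param n_draws Random draws retained for downstream analyses.
#' @param hpd_mass HPD probability mass.
#' @param seed Optional integer seed.
#' @return A list of class `trait_model_config`.
#' @export
trait_model_config <- function(n_chains = 4, n_iter = 5000, n_draws = 100,
                               hpd_mass = 0.95, seed = NULL) {
  keep <- n_chains * (n_iter - floor(n_iter / 2))
  if (n_draws > keep) stop("'n_draws' exceeds saved samples", call. = FALSE)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_draws = n_draws,
                 hpd_mass = hpd_mass, seed = seed),
            class = "trait_model_config")
}

# Gibbs sampler for y_ij = mu + u_j + e_ij with
#   mu ~ N(m0, s0^2), u_j ~ N(0, tau^2), e_ij ~ N(0, sigma_e^2),
#   tau, sigma_e ~ half-Cauchy(0, A) via the inverse-gamma mixture
#   sigma^2 | a ~ IG(1/2, 1/a), a ~ IG(1/2, 1/A^2).
# With sigma_fixed set, sigma_e is held at that value (used for species with
# a single observation and in conjugate cross-checks).
gibbs_hier_mean <- function(y, site, m0, s0, A, n_chains, n_iter,
                            random_effect = TRUE, sigma_fixed = NULL) {
  n <- length(y)
  site <- as.integer(factor(site))
  J <- max(site)
  if (J < 2L) random_effect <- FALSE
  n_j <- tabulate(site, J)
  warmup <- floor(n_iter / 2)
  keep <- n_iter - warmup
  out <- matrix(NA_real_, keep, n_chains)
  for (ch in seq_len(n_chains)) {
    mu <- mean(y)
    u <- rep(0, J)
    sig2e <- if (is.null(sigma_fixed)) max(stats::var(y), 1e-12) else
      sigma_fixed^2
    tau2 <- max(stats::var(y) / 2, 1e-12)
    a_e <- a_t <- 1
    s_j <- rowsum(y, site)[, 1]
    for (it in seq_len(n_iter)) {
      if (random_effect) {
        # blocked update: mu with the site effects integrated out
        # (site mean ybar_j ~ N(mu, tau^2 + sigma_e^2 / n_j)), then u | mu;
        # the centred one-at-a-time sweep mixes far too slowly for mu
        w <- n_j / (sig2e + n_j * tau2)
        prec <- 1 / s0^2 + sum(w)
        mn <- (m0 / s0^2 + sum(w * s_j / n_j)) / prec
        mu <- stats::rnorm(1, mn, sqrt(1 / prec))
        # site effects
        prec_u <- 1 / tau2 + n_j / sig2e
        u <- stats::rnorm(J, ((s_j - n_j * mu) / sig2e) / prec_u,
                          sqrt(1 / prec_u))
        # site variance (half-Cauchy via IG mixture)
        tau2 <- 1 / stats::rgamma(1, (J + 1) / 2,
                                  rate = 1 / a_t + sum(u^2) / 2)
        a_t <- 1 / stats::rgamma(1, 1, rate = 1 / A^2 + 1 / tau2)
      } else {
        prec <- 1 / s0^2 + n / sig2e
        mn <- (m0 / s0^2 + sum(y) / sig2e) / prec
        mu <- stats::rnorm(1, mn, sqrt(1 / prec))
      }
      if (is.null(sigma_fixed)) {
        r <- y - mu - if (random_effect) u[site] else 0
        sig2e <- 1 / stats::rgamma(1, (n + 1) / 2,
                                   rate = 1 / a_e + sum(r^2) / 2)
        a_e <- 1 / stats::rgamma(1, 1, rate = 1 / A^2 + 1 / sig2e)
      }
      if (it > warmup) out[it - warmup, ch] <- mu
    }
  }
  as.vector(out)
}

#' Posterior distribution of a species mean for one trait
#'
#' Fits `y_ij = mu + u_site(j) + e_ij` by Gibbs sampling, with a
#' data-informed normal prior on the species mean (centred at the observed
#' mean with the observed standard deviation, overridable) and
#' weakly-informative half-Cauchy priors on the site and residual standard
#' deviations. With a single site the random effect is dropped; with a
#' single observation a conjugate normal update is used with the residual
#' standard deviation fixed at `sigma_fixed`.
#'
#' @param values Numeric vector of observations for one species x trait.
#' @param sites Site labels, same length as `values`.
#' @param config A [trait_model_config()].
#' @param prior_mean,prior_sd Normal prior on the species mean; default the
#'   sample mean and sd of `values`.
#' @param sigma_fixed Fixed residual sd used when only one observation is
#'   available (typically the cross-species median residual sd).
#' @param species,variable Labels carried into the result.
#' @return A list of class `draw_set`: `species`, `variable`, `draws`
#'   (length `n_draws`), `posterior_mean`, `hpd_low`, `hpd_high`, and the
#'   full `samples` vector.
#' @export
fit_species_trait <- function(values, sites = rep(1L, length(values)),
                              config = trait_model_config(),
                              prior_mean = NULL, prior_sd = NULL,
                              sigma_fixed = NULL,
                              species = NA_character_,
                              variable = NA_character_) {
  ok <- !is.na(values)
  values <- values[ok]
  sites <- sites[ok]
  n <- length(values)
  if (n == 0L) stop("no observations", call. = FALSE)
  m0 <- if (is.null(prior_mean)) mean(values) else prior_mean
  s0 <- if (is.null(prior_sd)) stats::sd(values) else prior_sd

  n_saved <- config$n_chains * (config$n_iter - floor(config$n_iter / 2))
  if (n >= 2L && stats::sd(values) == 0 && (is.na(s0) || s0 <= 0)) {
    warning("zero variance in data; posterior collapses to a point",
            call. = FALSE)
    v <- values[1]
    samples <- rep(v, n_saved)
    return(new_draw_set(species, variable, rep(v, config$n_draws), v,
                        c(v, v), samples))
  }
  if (is.na(s0) || s0 <= 0) {
    if (is.null(sigma_fixed)) {
      stop("prior sd undefined (single observation?); supply 'prior_sd' or 'sigma_fixed'",
           call. = FALSE)
    }
    s0 <- sigma_fixed
  }

  samples <- with_seed(config$seed, {
    if (n == 1L) {
      if (is.null(sigma_fixed)) {
        stop("single observation requires 'sigma_fixed'", call. = FALSE)
      }
      prec <- 1 / s0^2 + 1 / sigma_fixed^2
      mn <- (m0 / s0^2 + values / sigma_fixed^2) / prec
      stats::rnorm(n_saved, mn, sqrt(1 / prec))
    } else {
      gibbs_hier_mean(values, sites, m0, s0, A = max(s0, 1e-8),
                      n_chains = config$n_chains, n_iter = config$n_iter,
                      sigma_fixed = sigma_fixed)
    }
  })
  hpd <- hpd_interval(samples, config$hpd_mass)
  draws <- subsample_draws(samples, config$n_draws,
                           seed = sub_seed(config$seed, 99L))
  new_draw_set(species, variable, draws, mean(samples), hpd, samples)
}

new_draw_set <- function(species, variable, draws, posterior_mean, hpd,
                         samples = NULL) {
  structure(list(species = species, variable = variable, draws = draws,
                 posterior_mean = posterior_mean,
                 hpd_low = hpd[[1]], hpd_high = hpd[[2]],
                 samples = samples),
            class = "draw_set")
}

#' @export
print.draw_set <- function(x, ...) {
  cat(sprintf("draw_set %s / %s: mean %.4g, 95%% HPD [%.4g, %.4g], %d draws\n",
              x$species, x$variable, x$posterior_mean, x$hpd_low,
              x$hpd_high, length(x$draws)))
  invisible(x)
}

#' Fit the species-trait model across all species and traits
#'
#' Applies the log transform (except exempt traits), fits
#' [fit_species_trait()] per species x trait, and collects the summary and
#' draw tables consumed by the evolutionary analyses. Species with a single
#' observation are fit conjugately with the residual sd fixed at the
#' cross-species median within-species sd for that trait.
#'
#' @param observations Data frame with `species`, `site` and one column per
#'   trait (individual-level measurements).
#' @param traits Trait columns to fit (default: all non-id columns).
#' @param config A [trait_model_config()].
#' @param log_transform Apply [transform_trait()] before fitting?
#' @param log_exempt Traits exempt from the log transform.
#' @return List with `summary` (species, variable, posterior_mean, hpd_low,
#'   hpd_high, n_obs) and `draws` (species, variable, draw_index, value).
#' @export
fit_all_species <- function(observations,
                            traits = NULL,
                            config = trait_model_config(),
                            log_transform = TRUE,
                            log_exempt = c("d13C", "delta13C")) {
  id_cols <- c("species", "site", "individual")
  if (is.null(traits)) traits <- setdiff(names(observations), id_cols)
  summ <- list()
  drws <- list()
  for (tr in traits) {
    vals <- observations[[tr]]
    if (log_transform) vals <- transform_trait(vals, tr, log_exempt)
    # cross-species median within-species sd: residual scale for n = 1 fits
    sds <- tapply(vals, observations$species,
                  function(v) stats::sd(v[!is.na(v)]))
    sigma_med <- stats::median(sds, na.rm = TRUE)
    if (!is.finite(sigma_med) || sigma_med <= 0) sigma_med <- 1
    for (sp in unique(observations$species)) {
      sel <- observations$species == sp & !is.na(vals)
      if (!any(sel)) next
      cfg <- config
      cfg$seed <- sub_seed(config$seed,
                           match(tr, traits) * 1000L +
                             match(sp, unique(observations$species)))
      fit <- fit_species_trait(
        vals[sel], observations$site[sel], cfg,
        sigma_fixed = if (sum(sel) == 1L) sigma_med else NULL,
        prior_sd = if (sum(sel) == 1L) sigma_med else NULL,
        species = sp, variable = tr)
      summ[[length(summ) + 1L]] <- data.frame(
        species = sp, variable = tr, posterior_mean = fit$posterior_mean,
        hpd_low = fit$hpd_low, hpd_high = fit$hpd_high, n_obs = sum(sel),
        stringsAsFactors = FALSE)
      drws[[length(drws) + 1L]] <- data.frame(
        species = sp, variable = tr,
        draw_index = seq_along(fit$draws), value = fit$draws,
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summ), draws = do.call(rbind, drws))
}
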