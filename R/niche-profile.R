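#' Square-root transform of a climate variable, with exemptions
#'
#' Climate variables are square-root transformed before profiling except
#' those in `exempt` (by default the July minimum temperature, `t_min`,
#' which can be negative).
#'
#' @param values Numeric vector.
#' @param variable Climate variable name.
#' @param exempt Variables left untransformed.
#' @return Transformed values.
#' @export
transform_climate <- function(values, variable, exempt = "t_min") {
  if (variable %in% exempt) return(values)
  bad <- which(!is.na(values) & values < 0)
  if (length(bad)) {
    stop(sprintf("negative value for sqrt-transformed variable '%s' at record(s) %s",
                 variable, paste(utils::head(bad, 10), collapse = ", ")),
         call. = FALSE)
  }
  sqrt(values)
}

#' Configuration for climatic-niche occupancy profiles
#'
#' Defaults mirror the published analysis: 10,000 probability-weighted
#' samples per species x variable, 95% HPD truncation (retaining about
#' 9,500 samples) and 100 random draws from the retained set.
#'
#' @param n_samples Occupancy-weighted samples drawn per profile.
#' @param hpd_mass HPD mass used for truncation.
#' @param n_draws Random draws retained from the truncated sample.
#' @param sqrt_exempt Variables exempt from the square-root transform.
#' @param seed Optional integer seed.
#' @return A list of class `niche_profile_config`.
#' @export
niche_profile_config <- function(n_samples = 10000, hpd_mass = 0.95,
                                 n_draws = 100, sqrt_exempt = "t_min",
                                 seed = NULL) {
  structure(list(n_samples = n_samples, hpd_mass = hpd_mass,
                 n_draws = n_draws, sqrt_exempt = sqrt_exempt, seed = seed),
            class = "niche_profile_config")
}

#' Sample a species' climatic-niche occupancy profile
#'
#' Draws `n_samples` grid-cell climate values with probability proportional
#' to the cell's occupancy probability, computes the HPD interval of the
#' sampled values, retains only samples inside it (about `hpd_mass` of
#' them), and reports the mean of the retained samples plus `n_draws`
#' random retained samples. The square-root transform is applied to the
#' cell values first unless the variable is exempt.
#'
#' @param surface Data frame for one species with columns `probability`
#'   and `variable` (plus anything else, ignored), e.g. from
#'   [simulate_occupancy()].
#' @param variable Name of the climate column to profile.
#' @param config A [niche_profile_config()].
#' @param transform Apply [transform_climate()] before sampling?
#' @param species Label carried into the result.
#' @return A `draw_set` (see [fit_species_trait()]); `samples` holds the
#'   retained (post-truncation) samples and the attribute `n_retained`
#'   their count.
#' @export
sample_profile <- function(surface, variable,
                           config = niche_profile_config(),
                           transform = TRUE, species = NA_character_) {
  p <- surface$probability
  if (is.null(p) || is.null(surface[[variable]])) {
    stop("surface must have 'probability' and the requested variable",
         call. = FALSE)
  }
  if (any(p < 0)) stop("negative occupancy probability", call. = FALSE)
  if (sum(p) <= 0) stop("all-zero occupancy probabilities", call. = FALSE)
  vals <- surface[[variable]]
  if (transform) vals <- transform_climate(vals, variable,
                                           config$sqrt_exempt)
  smp <- with_seed(config$seed, {
    vals[sample.int(length(vals), config$n_samples, replace = TRUE,
                    prob = p)]
  })
  if (length(unique(smp)) == 1L) {
    # degenerate single-cell profile: zero-width HPD, all samples retained
    out <- new_draw_set(species, variable, rep(smp[1], config$n_draws),
                        smp[1], c(smp[1], smp[1]), smp)
    attr(out, "n_retained") <- length(smp)
    return(out)
  }
  hpd <- hpd_interval(smp, config$hpd_mass)
  retained <- smp[smp >= hpd[1] & smp <= hpd[2]]
  draws <- subsample_draws(retained, min(config$n_draws, length(retained)),
                           seed = sub_seed(config$seed, 99L))
  out <- new_draw_set(species, variable, draws, mean(retained), hpd,
                      retained)
  attr(out, "n_retained") <- length(retained)
  out
}

#' Profile all species and climate variables of an occupancy set
#'
#' @param occupancy Named list (per climate variable) of named lists (per
#'   species) of surfaces, as produced by [simulate_study()], or a single
#'   named list of per-species surfaces if `variables` is given.
#' @param config A [niche_profile_config()].
#' @param variables Climate variables to profile; default all in
#'   `occupancy`.
#' @param transform Apply the square-root transform (set `FALSE` when the
#'   surfaces already hold analysis-scale values, as the synthetic
#'   generator's do).
#' @return List with `summary` and `draws` tables shaped like
#'   [fit_all_species()] output.
#' @export
profile_all_species <- function(occupancy,
                                config = niche_profile_config(),
                                variables = names(occupancy),
                                transform = TRUE) {
  summ <- list()
  drws <- list()
  for (v in variables) {
    per_sp <- occupancy[[v]]
    for (sp in names(per_sp)) {
      cfg <- config
      cfg$seed <- sub_seed(config$seed,
                           match(v, variables) * 1000L +
                             match(sp, names(per_sp)))
      ds <- sample_profile(per_sp[[sp]], v, cfg, transform = transform,
                           species = sp)
      summ[[length(summ) + 1L]] <- data.frame(
        species = sp, variable = v, posterior_mean = ds$posterior_mean,
        hpd_low = ds$hpd_low, hpd_high = ds$hpd_high,
        n_obs = attr(ds, "n_retained"), stringsAsFactors = FALSE)
      drws[[length(drws) + 1L]] <- data.frame(
        species = sp, variable = v, draw_index = seq_along(ds$draws),
        value = ds$draws, stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summ), draws = do.call(rbind, drws))
}
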