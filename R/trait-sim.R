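#' Simulate correlated trait evolution under Brownian motion
#'
#' Draws one tip value per species and trait from the matrix-normal
#' distribution implied by multivariate Brownian motion on a tree: row
#' covariance `C` (the phylogenetic covariance matrix of shared branch
#' lengths) and column covariance `R` (the evolutionary rate matrix, with
#' rates sigma^2 on the diagonal and between-trait covariances off it),
#' centred at the root state.
#'
#' @param tree A `phylo` object with nonnegative branch lengths.
#' @param R Symmetric positive-definite trait covariance matrix (p x p).
#' @param root_state Numeric vector of length p (recycled if length 1).
#' @param seed Optional integer seed.
#' @return Numeric matrix (n tips x p traits) with species rownames; column
#'   names taken from `R` or `trait1..traitp`.
#' @export
simulate_bm_traits <- function(tree, R, root_state = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  R <- as.matrix(R)
  p <- ncol(R)
  if (!isTRUE(all.equal(R, t(R)))) {
    stop("'R' must be symmetric", call. = FALSE)
  }
  LR <- tryCatch(chol(R), error = function(e) {
    stop("'R' must be positive-definite", call. = FALSE)
  })
  root_state <- rep_len(root_state, p)
  C <- phylo_vcv(tree)
  n <- nrow(C)
  # matrix square root of C via eigendecomposition: tolerates the singular
  # (zero-branch-length) limit where chol() would fail
  ec <- eigen(C, symmetric = TRUE)
  lam <- pmax(ec$values, 0)
  LC <- ec$vectors %*% (sqrt(lam) * t(ec$vectors))
  X <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  out <- sweep(LC %*% X %*% LR, 2L, root_state, "+")
  rownames(out) <- rownames(C)
  colnames(out) <- if (!is.null(colnames(R))) colnames(R) else
    paste0("trait", seq_len(p))
  out
}

#' Simulate individual-level trait observations
#'
#' Layers a site random effect and residual noise on species means:
#' `value = species_mean + site_effect + residual`, with the site effect
#' shared by all individuals within a (species, site) combination.
#'
#' @param species_means Matrix of species means (species x traits, with
#'   dimnames), e.g. from [simulate_bm_traits()].
#' @param n_sites_per_species Sites sampled per species.
#' @param n_individuals_per_site Individuals measured per site.
#' @param site_sd Standard deviation of the site effect (>= 0).
#' @param resid_sd Residual standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return A data frame with columns `species`, `site`, `individual` and one
#'   column per trait.
#' @export
simulate_observations <- function(species_means, n_sites_per_species = 2,
                                  n_individuals_per_site = 8,
                                  site_sd = 0.3, resid_sd = 0.3,
                                  seed = NULL) {
  if (site_sd < 0 || resid_sd < 0) {
    stop("'site_sd' and 'resid_sd' must be >= 0", call. = FALSE)
  }
  species_means <- as.matrix(species_means)
  sp <- rownames(species_means)
  traits <- colnames(species_means)
  ns <- n_sites_per_species
  ni <- n_individuals_per_site
  with_seed(seed, {
    rows <- lapply(seq_along(sp), function(i) {
      site_eff <- matrix(stats::rnorm(ns * length(traits), 0, site_sd),
                         ns, length(traits))
      df <- expand.grid(individual = seq_len(ni), site = seq_len(ns),
                        KEEP.OUT.ATTRS = FALSE)
      vals <- matrix(rep(species_means[i, ], each = nrow(df)),
                     nrow(df), length(traits)) +
        site_eff[df$site, , drop = FALSE] +
        matrix(stats::rnorm(nrow(df) * length(traits), 0, resid_sd),
               nrow(df), length(traits))
      colnames(vals) <- traits
      cbind(data.frame(species = sp[i],
                       site = paste0(sp[i], "_site", df$site),
                       individual = df$individual,
                       stringsAsFactors = FALSE),
            as.data.frame(vals))
    })
    do.call(rbind, rows)
  })
}

#' Simulate a MaxEnt-like occupancy surface for one species
#'
#' Grid cells receive climate values drawn uniformly around the species'
#' niche centre and an occupancy probability that decays as a Gaussian
#' kernel with the (standardised) distance of the cell's climate from the
#' centre, rescaled so the best cell has probability 1 (raw, not summing
#' to 1, mirroring raw habitat-suitability output).
#'
#' @param species_niche_center Named numeric vector: niche centre per
#'   climate variable.
#' @param spread Positive numeric (recycled): niche breadth per variable.
#' @param n_cells Number of grid cells (>= 1).
#' @param seed Optional integer seed.
#' @return Data frame with `cell_id`, `probability` and one column per
#'   climate variable.
#' @export
simulate_occupancy <- function(species_niche_center, spread, n_cells,
                               seed = NULL) {
  if (n_cells < 1) stop("'n_cells' must be >= 1", call. = FALSE)
  if (any(spread <= 0)) stop("'spread' must be > 0", call. = FALSE)
  centre <- species_niche_center
  vars <- names(centre)
  if (is.null(vars)) vars <- paste0("clim", seq_along(centre))
  spread <- rep_len(spread, length(centre))
  with_seed(seed, {
    vals <- vapply(seq_along(centre), function(j) {
      stats::runif(n_cells, centre[j] - 4 * spread[j],
                   centre[j] + 4 * spread[j])
    }, numeric(n_cells))
    vals <- matrix(vals, nrow = n_cells)
    colnames(vals) <- vars
    z2 <- rowSums(sweep(sweep(vals, 2L, centre, "-"), 2L, spread, "/")^2)
    prob <- exp(-0.5 * z2)
    prob <- prob / max(prob)
    cbind(data.frame(cell_id = seq_len(n_cells), probability = prob),
          as.data.frame(vals))
  })
}

#' Simulate a complete synthetic study
#'
#' One call producing every input the pipeline consumes: a Yule species
#' tree, bootstrap-replicate stand-in trees, species trait means evolved by
#' correlated Brownian motion, individual-level observations with site and
#' residual noise, and unimodal occupancy surfaces whose niche centres are
#' themselves BM-evolved climate values on the same tree (so trait-climate
#' pairs can show correlated evolution).
#'
#' Defaults mirror the field design the pipeline targets: 58 species,
#' 2 sites per species with 8 individuals each, traits on the natural-log
#' scale with moderate intraspecific noise, and 100 bootstrap trees.
#'
#' @param n_taxa Number of species.
#' @param birth_rate Yule speciation rate.
#' @param R Trait/climate evolutionary covariance. Default: two traits and
#'   one climate variable with trait-climate evolutionary correlation 0.7.
#' @param root_state Root state vector.
#' @param n_boot Number of bootstrap-replicate trees.
#' @param n_sites_per_species,n_individuals_per_site,site_sd,resid_sd
#'   Observation design, see [simulate_observations()].
#' @param n_cells Grid cells per species occupancy surface.
#' @param niche_spread Niche breadth for occupancy surfaces.
#' @param climate_vars Names of the columns of `R` treated as climate
#'   variables (get occupancy surfaces instead of field observations).
#' @param seed Master seed; all stages draw from documented substreams.
#' @return A list with elements `tree`, `boot_trees`, `species_means`,
#'   `observations`, `occupancy` (named list of per-species surfaces) and
#'   the configuration used.
#' @export
simulate_study <- function(n_taxa = 58, birth_rate = 1,
                           R = NULL, root_state = 0,
                           n_boot = 100,
                           n_sites_per_species = 2,
                           n_individuals_per_site = 8,
                           site_sd = 0.3, resid_sd = 0.3,
                           n_cells = 400, niche_spread = 1,
                           climate_vars = "mat",
                           seed = 1) {
  if (is.null(R)) {
    vars <- c("height", "lma", "mat")
    R <- matrix(c(1,   0.5, 0.7,
                  0.5, 1,   0.2,
                  0.7, 0.2, 1), 3, 3, dimnames = list(vars, vars))
  }
  tree <- simulate_tree(n_taxa, birth_rate, seed = sub_seed(seed, 1L))
  boot <- bootstrap_trees(tree, n_trees = n_boot, seed = sub_seed(seed, 2L))
  means <- simulate_bm_traits(tree, R, root_state, seed = sub_seed(seed, 3L))
  trait_cols <- setdiff(colnames(means), climate_vars)
  obs <- simulate_observations(means[, trait_cols, drop = FALSE],
                               n_sites_per_species, n_individuals_per_site,
                               site_sd, resid_sd, seed = sub_seed(seed, 4L))
  occ <- list()
  for (v in intersect(climate_vars, colnames(means))) {
    occ[[v]] <- lapply(seq_len(nrow(means)), function(i) {
      simulate_occupancy(stats::setNames(means[i, v], v), niche_spread,
                         n_cells, seed = sub_seed(seed, 10000L + i))
    })
    names(occ[[v]]) <- rownames(means)
  }
  list(tree = tree, boot_trees = boot, species_means = means,
       observations = obs, occupancy = occ,
       config = list(n_taxa = n_taxa, birth_rate = birth_rate, R = R,
                     root_state = root_state, n_boot = n_boot,
                     n_sites_per_species = n_sites_per_species,
                     n_individuals_per_site = n_individuals_per_site,
                     site_sd = site_sd, resid_sd = resid_sd,
                     n_cells = n_cells, niche_spread = niche_spread,
                     climate_vars = climate_vars, seed = seed))
}
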