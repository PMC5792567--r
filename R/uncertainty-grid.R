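#' Nearest-rank percentile summary of correlation estimates
#'
#' Order statistics at the 2.5, 50 and 97.5 percent ranks using the
#' nearest-rank convention (the `ceiling(p * n)`-th sorted value).
#'
#' @param estimates Numeric vector (>= 1 value).
#' @param probs Percentile probabilities.
#' @return Named numeric vector of the order statistics.
#' @export
percentile_summary <- function(estimates, probs = c(0.025, 0.5, 0.975)) {
  estimates <- estimates[!is.na(estimates)]
  if (!length(estimates)) stop("no estimates", call. = FALSE)
  s <- sort(estimates)
  idx <- pmax(1L, ceiling(probs * length(s)))
  stats::setNames(s[idx], paste0("q", probs * 100))
}

#' Specification of one uncertainty design
#'
#' The four designs cross the trait source (posterior mean vs random
#' posterior draws) with the tree source (best tree vs bootstrap
#' replicates): 1x1, 1x100, 100x1, 100x100 at full published scale. `n_trait_draws`
#' and `n_trees` rescale the grid (e.g. a 5x5 desk-scale run).
#'
#' @param trait_source `"mean"` or `"draws"`.
#' @param tree_source `"best"` or `"bootstrap_set"`.
#' @param n_trait_draws Number of trait draws used when
#'   `trait_source = "draws"`.
#' @param n_trees Number of bootstrap trees used when
#'   `tree_source = "bootstrap_set"`.
#' @param full_cross For draws x bootstrap_set: evaluate the full
#'   `n_trait_draws x n_trees` cross product instead of pairing draw r with
#'   tree r (the default, which keeps the replicate count linear).
#' @return A list of class `grid_spec` with a `design` label.
#' @export
grid_spec <- function(trait_source = c("mean", "draws"),
                      tree_source = c("best", "bootstrap_set"),
                      n_trait_draws = 100, n_trees = 100,
                      full_cross = FALSE) {
  trait_source <- match.arg(trait_source)
  tree_source <- match.arg(tree_source)
  design <- paste0(if (trait_source == "mean") "1" else n_trait_draws,
                   "x",
                   if (tree_source == "best") "1" else n_trees)
  structure(list(trait_source = trait_source, tree_source = tree_source,
                 n_trait_draws = n_trait_draws, n_trees = n_trees,
                 full_cross = full_cross, design = design),
            class = "grid_spec")
}

# assemble the n x 2 matrix for pair (a, b) from a draws table
# (species, variable, draw_index, value) or a summary table
# (species, variable, posterior_mean)
pair_matrix <- function(draws, summary, pair, draw_index = NULL) {
  get_col <- function(v) {
    if (is.null(draw_index)) {
      rows <- summary[summary$variable == v, ]
      stats::setNames(rows$posterior_mean, rows$species)
    } else {
      rows <- draws[draws$variable == v & draws$draw_index == draw_index, ]
      if (!nrow(rows)) stop(sprintf("missing draw %d for variable '%s'",
                                    draw_index, v), call. = FALSE)
      stats::setNames(rows$value, rows$species)
    }
  }
  va <- get_col(pair[1])
  vb <- get_col(pair[2])
  sp <- intersect(names(va), names(vb))
  X <- cbind(va[sp], vb[sp])
  dimnames(X) <- list(sp, pair)
  X
}

#' Run pairwise correlated-evolution analyses across an uncertainty design
#'
#' For every variable pair, repeats the bivariate analysis across the
#' replicates the design demands (mean or draw r of each trait, best or
#' bootstrap tree r) and summarises the spread of correlation estimates at
#' the 2.5/50/97.5 percentiles. By default only the posterior-mean
#' correlation is computed per replicate; set `compute_bf = TRUE` to also
#' run the stepping-stone Bayes factor (slower).
#'
#' @param pairs Character matrix or list of length-2 vectors: variable
#'   pairs to analyse.
#' @param draws Long draws table (`species`, `variable`, `draw_index`,
#'   `value`), e.g. from [fit_all_species()] / [profile_all_species()].
#' @param summary Summary table with `species`, `variable`,
#'   `posterior_mean`.
#' @param best_tree A `phylo` object.
#' @param boot_trees A `multiPhylo` list (required for bootstrap designs).
#' @param spec A [grid_spec()].
#' @param engine_config An [ss_config()] controlling the per-replicate
#'   MCMC (and stepping stone when `compute_bf`).
#' @param compute_bf Also compute logBF per replicate?
#' @return List with `summary` (pair, design, q2.5, q50, q97.5,
#'   n_estimates) and `estimates` (raw per-replicate rows for plotting).
#' @export
run_grid <- function(pairs, draws, summary, best_tree, boot_trees = NULL,
                     spec = grid_spec(), engine_config = ss_config(),
                     compute_bf = FALSE) {
  if (is.matrix(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  }
  use_draws <- spec$trait_source == "draws"
  use_boot <- spec$tree_source == "bootstrap_set"
  if (use_boot) {
    if (is.null(boot_trees)) stop("bootstrap design needs 'boot_trees'",
                                  call. = FALSE)
    if (length(boot_trees) < spec$n_trees) {
      stop(sprintf("need %d bootstrap trees, have %d", spec$n_trees,
                   length(boot_trees)), call. = FALSE)
    }
  }
  if (use_draws && !is.null(draws) &&
      max(draws$draw_index) < spec$n_trait_draws) {
    stop(sprintf("need %d trait draws, have %d", spec$n_trait_draws,
                 max(draws$draw_index)), call. = FALSE)
  }
  # replicate plan: (draw index or NA, tree index or NA)
  plan <- if (!use_draws && !use_boot) {
    data.frame(draw = NA_integer_, tree = NA_integer_)
  } else if (!use_draws && use_boot) {
    data.frame(draw = NA_integer_, tree = seq_len(spec$n_trees))
  } else if (use_draws && !use_boot) {
    data.frame(draw = seq_len(spec$n_trait_draws), tree = NA_integer_)
  } else if (spec$full_cross) {
    expand.grid(draw = seq_len(spec$n_trait_draws),
                tree = seq_len(spec$n_trees))
  } else {
    if (spec$n_trait_draws != spec$n_trees) {
      stop("paired draws x trees design needs n_trait_draws == n_trees",
           call. = FALSE)
    }
    data.frame(draw = seq_len(spec$n_trait_draws),
               tree = seq_len(spec$n_trees))
  }
  est_rows <- list()
  summ_rows <- list()
  for (pr in pairs) {
    lab <- paste(pr, collapse = ":")
    vals <- numeric(nrow(plan))
    bfs <- rep(NA_real_, nrow(plan))
    for (r in seq_len(nrow(plan))) {
      di <- plan$draw[r]
      ti <- plan$tree[r]
      X <- pair_matrix(draws, summary, pr,
                       draw_index = if (is.na(di)) NULL else di)
      tr <- if (is.na(ti)) best_tree else boot_trees[[ti]]
      # one engine seed per pair: replicate-to-replicate variation comes
      # from the inputs (draws, trees), so identical inputs give identical
      # estimates
      cfg <- engine_config
      cfg$seed <- sub_seed(engine_config$seed,
                           match(lab, vapply(pairs, paste, "",
                                             collapse = ":")))
      post <- run_mcmc(X, tr, "dependent", cfg)
      vals[r] <- mean(post$rho)
      if (compute_bf) {
        cfg_d <- cfg; cfg_d$seed <- sub_seed(cfg$seed, 1L)
        cfg_i <- cfg; cfg_i$seed <- sub_seed(cfg$seed, 2L)
        bfs[r] <- log_bayes_factor(
          stepping_stone(X, tr, "dependent", cfg_d),
          stepping_stone(X, tr, "independent", cfg_i))
      }
    }
    q <- percentile_summary(vals)
    est_rows[[lab]] <- data.frame(pair = lab, design = spec$design,
                                  replicate = seq_len(nrow(plan)),
                                  draw = plan$draw, tree = plan$tree,
                                  rho = vals, logBF = bfs,
                                  stringsAsFactors = FALSE)
    summ_rows[[lab]] <- data.frame(pair = lab, design = spec$design,
                                   q2.5 = q[[1]], q50 = q[[2]],
                                   q97.5 = q[[3]],
                                   n_estimates = nrow(plan),
                                   stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(summ_rows, make.row.names = FALSE)),
       estimates = do.call(rbind, c(est_rows, make.row.names = FALSE)))
}
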