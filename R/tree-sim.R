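#' Simulate a pure-birth (Yule) phylogeny
#'
#' Forward simulation of a Yule process: starting from the root split (two
#' lineages), each lineage speciates at rate `birth_rate`; simulation stops
#' when `n_taxa` lineages are alive and tips are extended by one further
#' exponential waiting time with rate `n_taxa * birth_rate`. Branch lengths
#' are in expected substitutions per site (the tree is not rescaled to unit
#' depth). The expected root-to-tip depth is `sum(1/(k * birth_rate))` for
#' `k = 2 .. n_taxa`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `phylo` with tip labels `s1 .. s<n>`.
#' @examples
#' tr <- simulate_tree(10, birth_rate = 1, seed = 1)
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 2) {
    stop("'n_taxa' must be a single integer >= 2", call. = FALSE)
  }
  if (birth_rate <= 0) stop("'birth_rate' must be > 0", call. = FALSE)
  n_taxa <- as.integer(n_taxa)
  with_seed(seed, {
    # active lineages: parent internal node id (1-based, creation order) and
    # birth time; internal node 1 is the root at time 0
    parent <- c(1L, 1L)
    birth <- c(0, 0)
    int_parent <- NA_integer_
    int_time <- 0
    k <- 2L
    t_now <- 0
    while (k < n_taxa) {
      t_now <- t_now + stats::rexp(1L, birth_rate * k)
      i <- sample.int(k, 1L)
      new_int <- length(int_time) + 1L
      int_parent[new_int] <- parent[i]
      int_time[new_int] <- t_now
      parent[i] <- new_int
      birth[i] <- t_now
      parent <- c(parent, new_int)
      birth <- c(birth, t_now)
      k <- k + 1L
    }
    t_end <- t_now + stats::rexp(1L, birth_rate * n_taxa)

    # serialise the recorded splits as Newick and let ape build the object
    fmt <- function(x) sprintf("%.15g", x)
    build <- function(id) {
      kids_int <- which(int_parent == id)
      kids_tip <- which(parent == id)
      parts <- c(
        vapply(kids_int, function(j) {
          paste0(build(j), ":", fmt(int_time[j] - int_time[id]))
        }, character(1)),
        vapply(kids_tip, function(i) {
          paste0("s", i, ":", fmt(t_end - birth[i]))
        }, character(1)))
      paste0("(", paste(parts, collapse = ","), ")")
    }
    ape::read.tree(text = paste0(build(1L), ";"))
  })
}

#' Perturb a tree by NNI moves and branch-length jitter
#'
#' Produces a bootstrap-replicate-like tree on the same taxa: `n_nni_moves`
#' random nearest-neighbour-interchange moves followed by independent
#' lognormal jitter of every branch length (jitter applied on the log scale,
#' so lengths stay positive).
#'
#' @param tree A `phylo` object.
#' @param n_nni_moves Number of random NNI moves (>= 0).
#' @param length_jitter_sd Standard deviation of the log-scale branch-length
#'   jitter (>= 0).
#' @param seed Optional integer seed.
#' @return A `phylo` object on the same taxa.
#' @export
perturb_tree <- function(tree, n_nni_moves = 0, length_jitter_sd = 0,
                         seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (n_nni_moves < 0 || length_jitter_sd < 0) {
    stop("'n_nni_moves' and 'length_jitter_sd' must be >= 0", call. = FALSE)
  }
  with_seed(seed, {
    out <- tree
    if (n_nni_moves > 0) {
      out <- phangorn::rNNI(out, moves = as.integer(n_nni_moves), n = 1L)
    }
    if (length_jitter_sd > 0) {
      out$edge.length <- out$edge.length *
        exp(stats::rnorm(length(out$edge.length), 0, length_jitter_sd))
    }
    out
  })
}

#' Generate a set of bootstrap-replicate stand-in trees
#'
#' @param tree A `phylo` object (the "best" tree).
#' @param n_trees Number of replicate trees.
#' @param n_nni_moves NNI moves per replicate.
#' @param length_jitter_sd Log-scale branch-length jitter per replicate.
#' @param seed Optional integer master seed; replicate r uses substream r.
#' @return A `multiPhylo` list of length `n_trees`.
#' @export
bootstrap_trees <- function(tree, n_trees = 100, n_nni_moves = 2,
                            length_jitter_sd = 0.1, seed = NULL) {
  out <- lapply(seq_len(n_trees), function(r) {
    perturb_tree(tree, n_nni_moves, length_jitter_sd,
                 seed = sub_seed(seed, 1000L + r))
  })
  class(out) <- "multiPhylo"
  out
}
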