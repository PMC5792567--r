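#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the covariance of tip values for taxa i and j is
#' proportional to their shared root-to-tip path length; the diagonal holds
#' each tip's depth. Taxa are ordered as in the input tree's tip labels.
#'
#' @param tree A `phylo` object with >= 2 tips and nonnegative branch
#'   lengths.
#' @return Symmetric n x n matrix with taxon dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 tips",
                                        call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length",
                                      call. = FALSE)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label]
}

# Shared depths (= C) and patristic distances between tips, used by the
# Ornstein-Uhlenbeck covariance on possibly non-ultrametric trees.
tip_depth_distance <- function(tree) {
  C <- phylo_vcv(tree)
  depth <- diag(C)
  D <- outer(depth, depth, "+") - 2 * C
  list(C = C, depth = depth, D = D)
}
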