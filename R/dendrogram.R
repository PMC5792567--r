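#' Convert an evolutionary correlation matrix to a distance matrix
#'
#' Default is the signed transform `d = 1 - rho`, so strongly negatively
#' correlated variables are far apart (distance up to 2); `"absolute"`
#' uses `d = 1 - |rho|`, grouping variables by strength regardless of sign.
#'
#' @param mat Symmetric correlation matrix with unit diagonal and entries
#'   in [-1, 1].
#' @param method `"signed"` (default) or `"absolute"`.
#' @return A `dist` object over the matrix labels.
#' @export
correlation_to_distance <- function(mat, method = c("signed", "absolute")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(mat) > 1 + 1e-8)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (any(abs(diag(mat) - 1) > 1e-8)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  d <- if (method == "signed") 1 - mat else 1 - abs(mat)
  diag(d) <- 0
  stats::as.dist(d)
}

#' Distance-based dendrogram over traits or climate variables
#'
#' Agglomerative clustering of the correlation-derived distances (UPGMA /
#' average linkage by default), used to identify suites of covarying
#' variables and to order the rows/columns of correlation figures.
#'
#' @param distances A `dist` object, e.g. from
#'   [correlation_to_distance()].
#' @param linkage `"average"` (UPGMA), `"complete"` or `"single"`.
#' @return A list of class `corr_dendrogram`: `hclust` (the fit),
#'   `leaf_order` (labels in plotting order) and `newick` (the dendrogram
#'   as a Newick string).
#' @export
build_dendrogram <- function(distances,
                             linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  hc <- stats::hclust(distances, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 newick = ape::write.tree(phy),
                 linkage = linkage),
            class = "corr_dendrogram")
}

#' @export
print.corr_dendrogram <- function(x, ...) {
  cat("correlation dendrogram (", x$linkage, " linkage)\n", sep = "")
  cat("leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Assemble a correlation matrix from pairwise results
#'
#' @param pair_results Data frame with `var_a`, `var_b`, `rho_estimate`
#'   (e.g. rows from [test_pair()]).
#' @param labels Variable order (default: order of appearance).
#' @return Symmetric matrix with unit diagonal.
#' @export
pair_correlation_matrix <- function(pair_results, labels = NULL) {
  if (is.null(labels)) {
    labels <- unique(c(pair_results$var_a, pair_results$var_b))
  }
  m <- diag(length(labels))
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(nrow(pair_results))) {
    a <- pair_results$var_a[i]
    b <- pair_results$var_b[i]
    m[a, b] <- m[b, a] <- pair_results$rho_estimate[i]
  }
  m
}

#' Bubble-matrix plot of pairwise evolutionary correlations
#'
#' Base-graphics matrix figure: circle size encodes |rho|, colour the sign
#' (blue positive, magenta negative), and opacity the support tier (none,
#' weak, moderate, strong). Rows/columns follow `order` (typically a
#' dendrogram leaf order).
#'
#' @param pair_results Data frame with `var_a`, `var_b`, `rho_estimate`
#'   and `support`.
#' @param order Optional label ordering.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the correlation matrix plotted.
#' @export
plot_correlation_matrix <- function(pair_results, order = NULL, ...) {
  m <- pair_correlation_matrix(pair_results)
  if (!is.null(order)) m <- m[order, order]
  labs <- rownames(m)
  n <- length(labs)
  sup <- matrix("none", n, n, dimnames = dimnames(m))
  for (i in seq_len(nrow(pair_results))) {
    a <- pair_results$var_a[i]
    b <- pair_results$var_b[i]
    sup[a, b] <- sup[b, a] <- as.character(pair_results$support[i])
  }
  alpha <- c(none = 0, weak = 0.3, moderate = 0.6, strong = 1)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0.5, n + 0.5),
                 xlab = "", ylab = "", axes = FALSE, asp = 1, ...)
  graphics::axis(1, seq_len(n), labs, las = 2, tick = FALSE)
  graphics::axis(2, seq_len(n), rev(labs), las = 2, tick = FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- m[i, j]
      col <- if (r >= 0) grDevices::rgb(0, 0, 1, alpha[sup[i, j]]) else
        grDevices::rgb(1, 0, 1, alpha[sup[i, j]])
      graphics::symbols(j, n + 1 - i, circles = abs(r) / 2.2,
                        inches = FALSE, add = TRUE, bg = col, fg = "grey70")
    }
  }
  invisible(m)
}
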