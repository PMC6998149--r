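#' Principal coordinate analysis (classical metric scaling)
#'
#' Eigendecomposition of the double-centred Gram matrix of a distance matrix.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported, not silently dropped; explained-variance
#' fractions are normalised over the positive eigenvalues only.
#'
#' @param d A symmetric `fmt_dist` (or plain labelled) distance matrix with a
#'   zero diagonal.
#' @return A `fmt_pcoa` object: list with `coordinates` (tibble `sample_id`,
#'   `PC1`, `PC2`, ...), `eigenvalues` (all of them, decreasing),
#'   `explained` (fraction of positive-eigenvalue variance per retained axis).
#' @export
pcoa <- function(d) {
  if (!is.matrix(d)) abort("`d` must be a distance matrix.")
  if (!isSymmetric(unname(unclass(d)), tol = 1e-8)) abort("`d` must be symmetric.")
  if (any(abs(diag(d)) > 1e-12)) abort("`d` must have a zero diagonal.")
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; that situation
  # is expected for non-Euclidean input and handled explicitly below
  fit <- suppressWarnings(cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(eig) * 1e-10
  coords <- fit$points[, seq_len(sum(pos[seq_len(ncol(fit$points))])), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(
    list(
      coordinates = bind_cols(tibble(sample_id = rownames(d)), as_tibble(coords)),
      eigenvalues = eig,
      explained = eig[seq_len(ncol(coords))] / sum(eig[eig > 0])
    ),
    class = "fmt_pcoa"
  )
}

#' @export
print.fmt_pcoa <- function(x, ...) {
  cat(sprintf(
    "# PCoA: %d samples, %d retained axes (%d negative eigenvalues)\n",
    nrow(x$coordinates), length(x$explained), sum(x$eigenvalues < 0)
  ))
  cat("# explained:", paste0(sprintf("%.1f%%", 100 * head(x$explained, 3)), collapse = ", "), "\n")
  print(x$coordinates, ...)
  invisible(x)
}

#' @describeIn pcoa Coordinates as a tibble.
#' @param x A `fmt_pcoa` object.
#' @param ... Unused.
#' @method tidy fmt_pcoa
#' @export
tidy.fmt_pcoa <- function(x, ...) x$coordinates

#' @describeIn pcoa One-row summary (axes retained, negative eigenvalues,
#'   variance captured by the top three axes).
#' @method glance fmt_pcoa
#' @export
glance.fmt_pcoa <- function(x, ...) {
  tibble(
    n_samples = nrow(x$coordinates),
    n_axes = length(x$explained),
    n_negative_eig = sum(x$eigenvalues < 0),
    explained_pc1 = x$explained[1],
    explained_top3 = sum(head(x$explained, 3))
  )
}

#' @describeIn pcoa Scatter of the first two principal coordinates; pass
#'   `colour_by`, a named vector keyed by sample id, to colour points.
#' @param object A `fmt_pcoa` object.
#' @param colour_by Optional named vector (sample id -> group label).
#' @method autoplot fmt_pcoa
#' @export
autoplot.fmt_pcoa <- function(object, colour_by = NULL, ...) {
  df <- object$coordinates
  if (!is.null(colour_by)) df$group <- unname(colour_by[df$sample_id])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation in a distance matrix:
#' `R = (mean between-group rank - mean within-group rank) / (N(N-1)/4)`, with
#' `p = (1 + #{permuted R >= observed}) / (1 + n_perm)` so p is never zero.
#' Delegates to [vegan::anosim()] under an explicit seed.
#'
#' @param d A `fmt_dist` distance matrix.
#' @param groups Group label per sample, in `rownames(d)` order (or a named
#'   vector keyed by sample id). At least two groups of two.
#' @param n_perm Number of permutations (the trial used 9999).
#' @param seed Integer seed for the permutations.
#' @return A `fmt_anosim` object with `statistic`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
anosim_test <- function(d, groups, n_perm = 9999, seed = NULL) {
  if (!is.matrix(d)) abort("`d` must be a distance matrix.")
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  if (length(groups) != nrow(d) || anyNA(groups)) {
    abort("`groups` must provide one non-NA label per sample in `d`.")
  }
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("ANOSIM needs >= 2 groups with >= 2 samples each.")
  }
  fit <- with_seed(seed, vegan::anosim(stats::as.dist(d), grouping = factor(groups),
                                       permutations = n_perm))
  structure(
    list(
      statistic = unname(fit$statistic),
      p_value = unname(fit$signif),
      n_permutations = n_perm,
      seed = seed
    ),
    class = "fmt_anosim"
  )
}

#' @export
print.fmt_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' @describeIn anosim_test One-row tibble of the test result.
#' @param x A `fmt_anosim` object.
#' @param ... Unused.
#' @method tidy fmt_anosim
#' @export
tidy.fmt_anosim <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_permutations = x$n_permutations)
}
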