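#' Shannon diversity (base-2)
#'
#' Entropy of a sample's taxon proportions, `H = -sum p_i log2 p_i` over taxa
#' with `p_i > 0`. Base 2 (bits) is the package default, matching the QIIME-1
#' convention under which the trial's diversity figures were produced; pass
#' `base` to switch.
#'
#' @param sample_counts Non-negative count (or abundance) vector with a
#'   positive total.
#' @param base Logarithm base (default 2).
#' @return Scalar diversity, `>= 0`.
#' @examples
#' shannon(c(1, 1, 2))  # 1.5 bits
#' @export
shannon <- function(sample_counts, base = 2) {
  assert_count_vector(sample_counts)
  p <- sample_counts[sample_counts > 0] / sum(sample_counts)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimate
#'
#' Nonparametric richness from singleton (`F1`) and doubleton (`F2`) counts:
#' the classic `S_obs + F1^2 / (2 F2)` when `F2 > 0`, the bias-corrected
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` when `F2 = 0`, and plain `S_obs` when
#' there are no singletons. Requires integer counts (the statistic is
#' undefined on proportions), so compute it on rarefied counts.
#'
#' @param sample_counts Non-negative integer vector with a positive total.
#' @return Scalar estimate, always `>=` observed richness.
#' @examples
#' chao1(c(rep(1, 4), rep(2, 2), rep(5, 4)))  # S_obs 10, F1 4, F2 2 -> 14
#' @export
chao1 <- function(sample_counts) {
  assert_count_vector(sample_counts)
  if (any(sample_counts != round(sample_counts))) {
    abort("`sample_counts` must be integers; Chao1 is undefined on proportions.")
  }
  s_obs <- sum(sample_counts > 0)
  f1 <- sum(sample_counts == 1)
  f2 <- sum(sample_counts == 2)
  if (f1 == 0) return(s_obs)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Per-sample alpha diversity
#'
#' @param table A feature table (rarefy first so depths are comparable).
#' @param base Logarithm base for Shannon (default 2).
#' @return Tibble `sample_id`, `shannon`, `chao1`, `observed` (taxa with
#'   nonzero count).
#' @export
alpha_diversity <- function(table, base = 2) {
  table <- as_ftbl_checked(table)
  m <- ft_matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(sprintf("Zero-total sample(s): %s.", paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  tibble(
    sample_id = rownames(m),
    shannon = unname(apply(m, 1, shannon, base = base)),
    chao1 = unname(apply(m, 1, chao1)),
    observed = unname(rowSums(m > 0))
  )
}

# ---- distance matrices ------------------------------------------------------

new_dist_matrix <- function(m, metric) {
  stopifnot(is.matrix(m), isSymmetric(unname(m)))
  structure(m, metric = metric, class = c("fmt_dist", "matrix", "array"))
}

#' @export
print.fmt_dist <- function(x, ...) {
  cat(sprintf("# %s matrix over %d samples\n", attr(x, "metric"), nrow(x)))
  print(unclass(round(x, 4)))
  invisible(x)
}

#' @describeIn bray_curtis Tidy a distance/similarity matrix into one row per
#'   unordered sample pair.
#' @param x A `fmt_dist` matrix.
#' @param ... Unused.
#' @method tidy fmt_dist
#' @export
tidy.fmt_dist <- function(x, ...) {
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    sample_1 = rownames(x)[pairs[, 1]],
    sample_2 = colnames(x)[pairs[, 2]],
    value = x[pairs],
    metric = attr(x, "metric")
  )
}

#' Bray-Curtis dissimilarity and abundance-based Sorensen similarity
#'
#' `bray_curtis()` computes `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on
#' relative abundances (so donor/recipient depth differences are irrelevant),
#' giving values in `[0, 1]`. `sorensen_similarity()` is its elementwise
#' complement `S = 1 - BC`, the trial's similarity index. Note the naming
#' collision: this abundance-based "Sorensen index" is *not* the classic
#' presence/absence Sorensen-Dice coefficient.
#'
#' @param table A feature table with at least two samples, none zero-total.
#' @param d A Bray-Curtis `fmt_dist` matrix.
#' @return A labelled symmetric `fmt_dist` matrix (zero diagonal for the
#'   dissimilarity, unit diagonal for the similarity).
#' @examples
#' ft <- feature_table(matrix(c(2, 1, 0, 0, 1, 3), 3, 2,
#'   dimnames = list(paste0("t", 1:3), c("a", "b"))))
#' bray_curtis(ft)["a", "b"]  # 0.75
#' @export
bray_curtis <- function(table) {
  table <- as_ftbl_checked(table)
  ra <- ra_matrix(table)
  if (nrow(ra) < 2) abort("Need >= 2 samples for pairwise dissimilarity.")
  d <- as.matrix(vegan::vegdist(ra, method = "bray"))
  new_dist_matrix(d, "Bray-Curtis dissimilarity")
}

#' @rdname bray_curtis
#' @export
sorensen_similarity <- function(d) {
  if (!inherits(d, "fmt_dist") && !is.matrix(d)) {
    abort("`d` must be a distance matrix from `bray_curtis()`.")
  }
  if (any(d < -1e-12 | d > 1 + 1e-12)) abort("Dissimilarities must lie in [0, 1].")
  s <- 1 - unclass(d)
  diag(s) <- 1
  new_dist_matrix(s, "Sorensen similarity (1 - Bray-Curtis)")
}

# similarity between two abundance/count vectors over the same taxa
sorensen_pair <- function(x, y) {
  px <- x / sum(x)
  py <- y / sum(y)
  1 - sum(abs(px - py)) / sum(px + py)
}

#' Unweighted UniFrac distance
#'
#' Presence/absence phylogenetic dissimilarity: the branch length unique to
#' either sample's taxon set divided by the branch length of their union.
#' Computed with [picante::unifrac()]; this wrapper enforces that every
#' observed taxon is a leaf of the tree.
#'
#' @param table A feature table.
#' @param tree Rooted `phylo` tree with branch lengths, leaves named like the
#'   table's taxa (see [read_phylogeny()]).
#' @return A `fmt_dist` matrix in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  table <- as_ftbl_checked(table)
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object.")
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    # resolve polytomies / root with zero-length edges; UniFrac is unchanged
    tree <- ape::multi2di(tree)
  }
  m <- ft_matrix(table)
  observed <- colnames(m)[colSums(m) > 0]
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing)) {
    abort(sprintf("Taxa absent from the tree: %s", paste(missing, collapse = ", ")))
  }
  m <- m[, intersect(colnames(m), tree$tip.label), drop = FALSE]
  d <- as.matrix(picante::unifrac(m, tree))
  d <- d[rownames(m), rownames(m)]
  d[is.na(d)] <- 0
  new_dist_matrix(d, "unweighted UniFrac")
}
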