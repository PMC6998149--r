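#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads to exactly `depth` reads *without*
#' replacement (multivariate hypergeometric), the behaviour of classic QIIME-1
#' rarefaction. Samples whose total is below `depth` cannot be rarefied and are
#' dropped; the drop list is part of the return contract (attribute
#' `"dropped"`, see [dropped_samples()]) so cohort bookkeeping stays explicit.
#'
#' @param table A feature table.
#' @param depth Target reads per sample (default 29000, the depth used for the
#'   trial's diversity analyses). Must be >= 1.
#' @param seed Integer seed; identical seed and input give bit-identical
#'   output. The caller's RNG state is left untouched.
#' @return A feature table in which every retained sample totals exactly
#'   `depth`. Attributes: `"dropped"` (tibble `sample_id`, `total` of excluded
#'   samples) and `"rarefaction_depth"`.
#' @examples
#' ft <- feature_table(matrix(c(8, 2, 5, 0), 2, 2,
#'   dimnames = list(c("t1", "t2"), c("S1", "S2"))))
#' rf <- rarefy_table(ft, depth = 5, seed = 1)
#' sample_totals(rf)
#' @export
rarefy_table <- function(table, depth = 29000, seed = NULL) {
  table <- as_ftbl_checked(table)
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1 || depth != round(depth)) {
    abort("`depth` must be a single integer >= 1.")
  }
  depth <- as.integer(depth)
  m <- ft_matrix(table)
  tot <- rowSums(m)
  keep <- tot >= depth
  dropped <- tibble(sample_id = rownames(m)[!keep], total = unname(tot[!keep]))
  if (nrow(dropped)) {
    rlang::inform(sprintf(
      "Dropped %d sample(s) below depth %d: %s",
      nrow(dropped), depth, paste(dropped$sample_id, collapse = ", ")
    ))
  }
  m <- m[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(m, 1, subsample_without_replacement, depth = depth))
  })
  if (nrow(m) == 1) out <- matrix(out, nrow = 1, dimnames = dimnames(m)) else dimnames(out) <- dimnames(m)
  lin <- if ("lineage" %in% names(table)) {
    d <- distinct(table, .data$taxon_id, .data$lineage)
    setNames(d$lineage, d$taxon_id)
  }
  res <- feature_table(t(out), lineage = lin)
  attr(res, "dropped") <- dropped
  attr(res, "rarefaction_depth") <- depth
  res
}

# draw `depth` reads without replacement from a count vector
subsample_without_replacement <- function(x, depth) {
  tot <- sum(x)
  if (tot == depth) return(x)
  picked <- sample.int(tot, depth)
  # map read indices to taxa via the cumulative count boundaries
  taxon_of <- findInterval(picked - 1L, cumsum(c(0L, x)), rightmost.closed = FALSE)
  tabulate(taxon_of, nbins = length(x))
}

#' Samples dropped during rarefaction
#'
#' @param table A rarefied feature table from [rarefy_table()].
#' @return Tibble `sample_id`, `total` (empty if nothing was dropped).
#' @export
dropped_samples <- function(table) {
  attr(table, "dropped") %||% tibble(sample_id = character(), total = numeric())
}
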