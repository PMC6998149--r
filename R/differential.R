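#' LEfSe-like differential-abundance screen
#'
#' Two-stage screen for taxa separating two groups, patterned after the LDA
#' effect size (LEfSe) pipeline but with a closed-form effect score so results
#' are exactly reproducible:
#'
#' 1. per-taxon Kruskal-Wallis test on relative abundances at level `alpha`;
#' 2. effect score on the LEfSe abundance axis (proportions rescaled to sum
#'    to 1e6): `score = sign(m_A - m_B) * log10(1 + |m_A - m_B| * 1e6)`,
#'    where `m_A`, `m_B` are group mean relative abundances.
#'
#' A taxon passes iff `p < alpha` and `|score| > score_threshold`. The
#' defaults (alpha 0.05, threshold 2) match the conventional LEfSe cut-offs.
#' Unlike full LEfSe there is no subclass consistency step and no bootstrapped
#' LDA, so the score is deterministic; `seed` is accepted for interface
#' stability and ignored.
#'
#' @param table A feature table (any taxonomic level; collapse first with
#'   [collapse_taxonomy()] if desired).
#' @param groups Group label per sample: a named vector keyed by sample id, or
#'   a vector in table sample order. Exactly two levels, each with >= 2
#'   samples.
#' @param alpha Stage-1 significance level (default 0.05).
#' @param score_threshold Minimum absolute effect score (default 2).
#' @param seed Ignored (see above).
#' @return Tibble, one row per taxon, sorted by decreasing `|score|` within
#'   the passing set first: `taxon_id`, `enriched_group`, `p_value`, `score`,
#'   `pass`.
#' @export
differential_taxa <- function(table, groups, alpha = 0.05, score_threshold = 2,
                              seed = NULL) {
  table <- as_ftbl_checked(table)
  ra <- ra_matrix(table)
  if (!is.null(names(groups))) groups <- groups[rownames(ra)]
  if (length(groups) != nrow(ra) || anyNA(groups)) {
    abort("`groups` must give one non-NA label per sample.")
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort("Exactly two groups are required.")
  if (any(table(groups) < 2)) abort("Each group needs >= 2 samples.")
  lv <- levels(groups)

  res <- purrr::map(colnames(ra), function(tx) {
    x <- ra[, tx]
    p <- if (length(unique(x)) == 1) 1 else
      suppressWarnings(kruskal.test(x, groups)$p.value)
    m_a <- mean(x[groups == lv[1]])
    m_b <- mean(x[groups == lv[2]])
    delta <- m_a - m_b
    score <- sign(delta) * log10(1 + abs(delta) * 1e6)
    tibble(
      taxon_id = tx,
      enriched_group = if (delta == 0) NA_character_ else if (delta > 0) lv[1] else lv[2],
      p_value = p,
      score = score
    )
  }) |> bind_rows()

  res |>
    mutate(pass = .data$p_value < alpha & abs(.data$score) > score_threshold) |>
    arrange(dplyr::desc(.data$pass), dplyr::desc(abs(.data$score)))
}

#' @describeIn differential_taxa Horizontal bar chart of passing taxa by
#'   signed effect score.
#' @param data Result tibble from `differential_taxa()`.
#' @export
plot_differential_taxa <- function(data) {
  df <- filter(data, .data$pass)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$taxon_id, .data$score),
    fill = .data$enriched_group
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "effect score (log10 scale)", y = NULL, fill = "enriched in") +
    ggplot2::theme_minimal()
}
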