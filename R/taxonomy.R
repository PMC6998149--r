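#' Collapse a feature table to a taxonomic rank
#'
#' Sums OTUs sharing the same lineage prefix down to `level` and optionally
#' pools rare taxa. Lineages use the `k__...;p__...;...` convention with `";"`
#' as delimiter. A taxon whose lineage is unassigned at `level` (missing or
#' empty component) is collapsed into `"unclassified <parent>"`, where
#' `<parent>` is its last assigned rank. After collapsing, taxa whose overall
#' mean relative abundance is `<= min_fraction` are pooled into `"other"`
#' (the trial's per-patient composition plots kept only taxa above 0.1%).
#' Per-sample totals are conserved exactly in all cases.
#'
#' @param table A feature table with a `lineage` column.
#' @param level Rank to collapse to: one of `"kingdom"`, `"phylum"`,
#'   `"class"`, `"order"`, `"family"`, `"genus"`, `"species"`.
#' @param min_fraction Pool taxa with overall mean relative abundance at or
#'   below this proportion into `"other"`. Default 0 (no pooling).
#' @return A feature table whose `taxon_id` is the collapsed lineage prefix.
#' @export
collapse_taxonomy <- function(table, level = "genus", min_fraction = 0) {
  table <- as_ftbl_checked(table)
  if (!"lineage" %in% names(table)) {
    abort("`table` has no lineage column; taxonomy is required to collapse.")
  }
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  if (!is.character(level) || !level %in% ranks) {
    abort(sprintf("Unknown rank '%s'; expected one of %s.",
                  as.character(level)[1], paste(ranks, collapse = ", ")))
  }
  k <- match(level, ranks)
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction >= 1) {
    abort("`min_fraction` must be in [0, 1).")
  }

  lin <- distinct(table, .data$taxon_id, .data$lineage)
  lin$group <- vapply(lin$lineage, collapse_lineage, character(1), k = k)

  collapsed <- table |>
    left_join(select(lin, "taxon_id", "group"), by = "taxon_id") |>
    group_by(.data$sample_id, taxon_id = .data$group) |>
    summarise(count = sum(.data$count), .groups = "drop")
  ft <- feature_table(
    collapsed,
    lineage = setNames(unique(lin$group), unique(lin$group))
  )

  if (min_fraction > 0) {
    ra <- ra_matrix(ft)
    mean_ra <- colMeans(ra)
    rare <- names(mean_ra)[mean_ra <= min_fraction]
    if (length(rare)) {
      pooled <- ft |>
        mutate(taxon_id = ifelse(.data$taxon_id %in% rare, "other", .data$taxon_id)) |>
        group_by(.data$sample_id, .data$taxon_id) |>
        summarise(count = sum(.data$count), .groups = "drop")
      keep_ids <- c(setdiff(ft_taxon_ids(ft), rare), "other")
      lin2 <- setNames(keep_ids, keep_ids)
      ft <- feature_table(pooled, lineage = lin2)
    }
  }
  ft
}

# truncate one lineage string to the first k ranks, labelling unassigned
# components "unclassified <last assigned>"
collapse_lineage <- function(lineage, k) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- stringr::str_trim(parts)
  assigned <- !is.na(parts) & !grepl("^[a-z]__\\s*$", parts) & parts != ""
  if (length(parts) >= k && assigned[k]) {
    return(paste(parts[seq_len(k)], collapse = ";"))
  }
  last <- if (any(assigned)) max(which(assigned)) else 0L
  if (last == 0L) return("unclassified")
  paste("unclassified", parts[last])
}
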