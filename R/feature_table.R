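#' Build a longitudinal feature (OTU) count table
#'
#' The central container of the package: a tidy long tibble with one row per
#' (sample, taxon) cell, integer counts, and an optional taxonomy lineage
#' string per taxon (`k__...;p__...;...` style). Sample and taxon ordering is
#' preserved from the input and carried through file round-trips.
#'
#' @param x Either a long data frame with columns `sample_id`, `taxon_id`,
#'   `count` (extra columns are ignored except `lineage`), or a numeric matrix
#'   with taxa as rows and samples as columns (the orientation of standard
#'   OTU-table TSVs).
#' @param lineage Optional named character vector mapping `taxon_id` to a
#'   taxonomy lineage string. Overrides any `lineage` column in `x`.
#'
#' @return A `fmt_ftbl` tibble with columns `sample_id`, `taxon_id`, `count`
#'   and (when taxonomy is known) `lineage`, containing the complete
#'   sample-by-taxon grid. Sample/taxon order is stored in attributes
#'   `sample_ids` / `taxon_ids`.
#' @examples
#' m <- matrix(c(5, 0, 1, 0, 2, 2), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
#' ft <- feature_table(m)
#' sample_totals(ft)
#' @export
feature_table <- function(x, lineage = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("Matrix input must have taxon rownames and sample colnames.")
    }
    long <- as_tibble(x, rownames = "taxon_id") |>
      tidyr::pivot_longer(-"taxon_id", names_to = "sample_id", values_to = "count") |>
      select("sample_id", "taxon_id", "count")
    sample_ids <- colnames(x)
    taxon_ids <- rownames(x)
  } else if (is.data.frame(x)) {
    need <- c("sample_id", "taxon_id", "count")
    if (!all(need %in% names(x))) {
      abort(sprintf(
        "Long input must have columns %s (missing: %s).",
        paste(need, collapse = ", "), paste(setdiff(need, names(x)), collapse = ", ")
      ))
    }
    long <- as_tibble(x)[intersect(c(need, "lineage"), names(x))]
    long$sample_id <- as.character(long$sample_id)
    long$taxon_id <- as.character(long$taxon_id)
    sample_ids <- unique(long$sample_id)
    taxon_ids <- unique(long$taxon_id)
    if (is.null(lineage) && "lineage" %in% names(long)) {
      lin <- distinct(long, .data$taxon_id, .data$lineage)
      if (anyDuplicated(lin$taxon_id)) {
        abort("Conflicting lineage strings for the same taxon_id.")
      }
      lineage <- setNames(lin$lineage, lin$taxon_id)
      long$lineage <- NULL
    }
    # complete the grid so every cell is addressable
    long <- tidyr::complete(
      long,
      sample_id = sample_ids, taxon_id = taxon_ids,
      fill = list(count = 0L)
    )
    if (anyDuplicated(paste(long$sample_id, long$taxon_id))) {
      abort("Duplicate (sample_id, taxon_id) cells in input.")
    }
  } else {
    abort("`x` must be a data frame or a taxa-by-samples matrix.")
  }

  if (anyNA(long$count) || !is.numeric(long$count)) {
    abort("Counts must be numeric and free of NA.")
  }
  if (any(long$count < 0)) abort("Counts must be non-negative.")
  if (any(long$count != round(long$count))) abort("Counts must be integral.")
  long$count <- as.integer(round(long$count))

  if (!is.null(lineage)) {
    missing_lin <- setdiff(taxon_ids, names(lineage))
    if (length(missing_lin)) {
      abort(sprintf("Lineage missing for taxa: %s",
                    paste(head(missing_lin, 5), collapse = ", ")))
    }
    long$lineage <- unname(lineage[long$taxon_id])
  }

  new_ftbl(long, sample_ids, taxon_ids)
}

new_ftbl <- function(long, sample_ids, taxon_ids) {
  long <- arrange(
    long,
    match(.data$sample_id, sample_ids),
    match(.data$taxon_id, taxon_ids)
  )
  structure(
    long,
    sample_ids = sample_ids,
    taxon_ids = taxon_ids,
    class = c("fmt_ftbl", class(tibble()))
  )
}

is_ftbl <- function(x) inherits(x, "fmt_ftbl")

as_ftbl_checked <- function(x, arg = "table") {
  if (is_ftbl(x)) return(x)
  if (is.data.frame(x) || is.matrix(x)) return(feature_table(x))
  abort(sprintf("`%s` must be a feature table (see `feature_table()`).", arg))
}

#' @export
print.fmt_ftbl <- function(x, ...) {
  cat(sprintf(
    "# Feature table: %d samples x %d taxa (%s taxonomy)\n",
    length(ft_sample_ids(x)), length(ft_taxon_ids(x)),
    if ("lineage" %in% names(x)) "with" else "no"
  ))
  NextMethod()
}

#' Sample and taxon identifiers of a feature table
#'
#' @param table A feature table from [feature_table()].
#' @return Character vector of ids in table order.
#' @export
ft_sample_ids <- function(table) {
  attr(table, "sample_ids") %||% unique(table$sample_id)
}

#' @rdname ft_sample_ids
#' @export
ft_taxon_ids <- function(table) {
  attr(table, "taxon_ids") %||% unique(table$taxon_id)
}

#' Feature table as a samples-by-taxa matrix
#'
#' @param table A feature table.
#' @return Integer matrix, samples in rows (table order), taxa in columns.
#' @export
ft_matrix <- function(table) {
  table <- as_ftbl_checked(table)
  s <- ft_sample_ids(table)
  t <- ft_taxon_ids(table)
  m <- matrix(0L, length(s), length(t), dimnames = list(s, t))
  m[cbind(match(table$sample_id, s), match(table$taxon_id, t))] <- table$count
  m
}

#' Per-sample sequencing totals
#'
#' @param table A feature table.
#' @return Tibble with columns `sample_id`, `total`.
#' @export
sample_totals <- function(table) {
  table <- as_ftbl_checked(table)
  table |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    arrange(match(.data$sample_id, ft_sample_ids(table)))
}

#' Relative abundances
#'
#' Converts counts to within-sample proportions. Each sample's proportions sum
#' to 1 (to numerical precision); a zero-total sample is an error because its
#' composition is undefined.
#'
#' @param table A feature table.
#' @return Tibble `sample_id`, `taxon_id`, `rel_abund` (plus `lineage` when
#'   present), same cell order as the input.
#' @examples
#' ft <- feature_table(matrix(c(1, 1, 2), 3, 1,
#'   dimnames = list(paste0("t", 1:3), "S1")))
#' relative_abundance(ft)
#' @export
relative_abundance <- function(table) {
  table <- as_ftbl_checked(table)
  tot <- sample_totals(table)
  zero <- tot$sample_id[tot$total == 0]
  if (length(zero)) {
    abort(sprintf("Zero-total sample(s): %s. Drop or rarefy first.",
                  paste(zero, collapse = ", ")))
  }
  out <- table |>
    left_join(tot, by = "sample_id") |>
    mutate(rel_abund = .data$count / .data$total) |>
    select(-"count", -"total")
  as_tibble(out)
}

# relative-abundance matrix, samples x taxa
ra_matrix <- function(table) {
  m <- ft_matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(sprintf("Zero-total sample(s): %s.",
                  paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  sweep(m, 1, tot, "/")
}
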