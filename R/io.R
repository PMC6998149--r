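#' Read and write feature tables (TSV and BIOM-JSON)
#'
#' TSV layout: first column `taxon_id`, one column of counts per sample, and an
#' optional final `taxonomy` column holding lineage strings. The BIOM dialect
#' is the "rich" JSON form (format 1.0.0) with sparse `[row, column, value]`
#' triples; the reader also accepts dense `matrix_type`. Both round-trip
#' counts, sample order and taxon order losslessly.
#'
#' @param path File to read or write.
#' @param format `"tsv"` or `"biom-json"`. `read_feature_table()` guesses from
#'   the extension (`.biom`/`.json` vs anything else) when omitted.
#' @param table A feature table.
#' @return `read_feature_table()` returns a feature table;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  format <- format %||%
    (if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) "biom-json" else "tsv")
  format <- rlang::arg_match(format, c("tsv", "biom-json"))
  if (format == "tsv") read_ft_tsv(path) else read_ft_biom(path)
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path, format = NULL) {
  table <- as_ftbl_checked(table)
  format <- format %||%
    (if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) "biom-json" else "tsv")
  format <- rlang::arg_match(format, c("tsv", "biom-json"))
  if (format == "tsv") write_ft_tsv(table, path) else write_ft_biom(table, path)
  invisible(path)
}

read_ft_tsv <- function(path) {
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort(sprintf("Failed to parse TSV %s: %s", path, conditionMessage(e)))
  )
  if (ncol(df) < 2) abort(sprintf("TSV %s needs a taxon column plus >= 1 sample column.", path))
  names(df)[1] <- "taxon_id"
  has_tax <- tolower(names(df)[ncol(df)]) == "taxonomy"
  lineage <- NULL
  if (has_tax) {
    lineage <- setNames(df[[ncol(df)]], df$taxon_id)
    df <- df[-ncol(df)]
  }
  sample_cols <- names(df)[-1]
  counts <- suppressWarnings(lapply(df[sample_cols], as.numeric))
  for (sc in sample_cols) {
    bad <- which(is.na(counts[[sc]]) & !is.na(df[[sc]]))
    if (length(bad)) {
      abort(sprintf("Non-numeric count in %s, column '%s', data line %d: '%s'",
                    path, sc, bad[1], df[[sc]][bad[1]]))
    }
    neg <- which(counts[[sc]] < 0)
    if (length(neg)) {
      abort(sprintf("Negative count in %s, column '%s', data line %d.",
                    path, sc, neg[1]))
    }
  }
  m <- do.call(cbind, counts)
  rownames(m) <- df$taxon_id
  feature_table(m, lineage = lineage)
}

write_ft_tsv <- function(table, path) {
  m <- t(ft_matrix(table))    # taxa x samples
  out <- as_tibble(m, rownames = "taxon_id")
  if ("lineage" %in% names(table)) {
    lin <- distinct(table, .data$taxon_id, .data$lineage)
    out$taxonomy <- lin$lineage[match(out$taxon_id, lin$taxon_id)]
  }
  readr::write_tsv(out, path, progress = FALSE)
}

read_ft_biom <- function(path) {
  b <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) abort(sprintf("Failed to parse BIOM-JSON %s: %s",
                                                  path, conditionMessage(e))))
  for (key in c("rows", "columns", "data", "matrix_type", "shape")) {
    if (is.null(b[[key]])) abort(sprintf("BIOM file %s lacks required key '%s'.", path, key))
  }
  taxa <- vapply(b$rows, function(r) as.character(r$id), character(1))
  samples <- vapply(b$columns, function(cl) as.character(cl$id), character(1))
  nr <- length(taxa); nc <- length(samples)
  if (!identical(as.integer(unlist(b$shape)), c(nr, nc))) {
    abort(sprintf("BIOM file %s: 'shape' disagrees with rows/columns lengths.", path))
  }
  m <- matrix(0, nr, nc, dimnames = list(taxa, samples))
  if (identical(b$matrix_type, "sparse")) {
    for (trip in b$data) {
      trip <- unlist(trip)
      if (length(trip) != 3) abort(sprintf("BIOM file %s: malformed sparse triple in 'data'.", path))
      m[trip[1] + 1, trip[2] + 1] <- trip[3]
    }
  } else if (identical(b$matrix_type, "dense")) {
    for (i in seq_len(nr)) m[i, ] <- unlist(b$data[[i]])
  } else {
    abort(sprintf("BIOM file %s: unsupported matrix_type '%s'.", path, b$matrix_type))
  }
  if (any(m < 0)) abort(sprintf("BIOM file %s: negative count.", path))
  lineage <- NULL
  lins <- vapply(b$rows, function(r) {
    tx <- r$metadata$taxonomy
    if (is.null(tx)) NA_character_ else paste(unlist(tx), collapse = ";")
  }, character(1))
  if (!all(is.na(lins))) lineage <- setNames(lins, taxa)
  feature_table(m, lineage = lineage)
}

write_ft_biom <- function(table, path) {
  m <- t(ft_matrix(table))    # taxa x samples
  lin <- if ("lineage" %in% names(table)) {
    d <- distinct(table, .data$taxon_id, .data$lineage)
    setNames(d$lineage, d$taxon_id)
  }
  rows <- lapply(rownames(m), function(tid) {
    md <- if (is.null(lin)) NULL else list(taxonomy = as.list(strsplit(lin[[tid]], ";", fixed = TRUE)[[1]]))
    list(id = tid, metadata = md)
  })
  cols <- lapply(colnames(m), function(sid) list(id = sid, metadata = NULL))
  idx <- which(m != 0, arr.ind = TRUE)
  data <- lapply(seq_len(nrow(idx)), function(k) {
    c(idx[k, 1] - 1L, idx[k, 2] - 1L, m[idx[k, 1], idx[k, 2]])
  })
  obj <- list(
    id = NULL,
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = paste0("fmtengraft ", as.character(packageVersion("fmtengraft"))),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    matrix_type = "sparse",
    matrix_element_type = "int",
    shape = c(nrow(m), ncol(m)),
    rows = rows,
    columns = cols,
    data = data
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Read per-sample trial metadata
#'
#' Metadata is a TSV with mandatory columns `sample_id`, `subject_id`, `role`
#' (`donor`/`recipient`), `arm` (`FMT`/`sham`/`none`), `timepoint` (one of
#' [trial_timepoints()]), and `donor_id` (the assigned donor for FMT
#' recipients; empty otherwise). Validation is strict: donors must carry
#' `arm = none` and `timepoint = donor`, and unknown timepoint labels are
#' rejected at load rather than passed downstream.
#'
#' @param path TSV file.
#' @return A validated tibble (see [sample_metadata()]).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  sample_metadata(df)
}

#' Validate trial sample metadata
#'
#' @param data Data frame with the columns documented in
#'   [read_sample_metadata()].
#' @return The validated metadata tibble.
#' @export
sample_metadata <- function(data) {
  need <- c("sample_id", "subject_id", "role", "arm", "timepoint")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(sprintf("Metadata lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  md <- as_tibble(data)
  if (!"donor_id" %in% names(md)) md$donor_id <- NA_character_
  md <- mutate(md, across(c("sample_id", "subject_id", "role", "arm",
                            "timepoint", "donor_id"), as.character))
  if (anyDuplicated(md$sample_id)) abort("Duplicate sample_id in metadata.")
  bad_role <- setdiff(unique(md$role), c("donor", "recipient"))
  if (length(bad_role)) abort(sprintf("Unknown role(s): %s", paste(bad_role, collapse = ", ")))
  bad_arm <- setdiff(unique(md$arm), c("FMT", "sham", "none"))
  if (length(bad_arm)) abort(sprintf("Unknown arm(s): %s", paste(bad_arm, collapse = ", ")))
  bad_tp <- setdiff(unique(md$timepoint), TIMEPOINTS)
  if (length(bad_tp)) {
    abort(sprintf("Unknown timepoint label(s): %s (valid: %s)",
                  paste(bad_tp, collapse = ", "), paste(TIMEPOINTS, collapse = ", ")))
  }
  donors <- filter(md, .data$role == "donor")
  if (any(donors$arm != "none") || any(donors$timepoint != "donor")) {
    abort("Donor samples must have arm = 'none' and timepoint = 'donor'.")
  }
  recip <- filter(md, .data$role == "recipient")
  if (any(recip$timepoint == "donor")) {
    abort("Recipient samples cannot carry the 'donor' timepoint.")
  }
  md
}

#' Read a rooted phylogeny for UniFrac
#'
#' Thin wrapper over [ape::read.tree()] that enforces what UniFrac needs:
#' unique leaf labels and non-negative branch lengths.
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(sprintf("Failed to parse Newick file %s.", path))
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (any(tree$edge.length < 0)) abort("Tree has negative branch lengths.")
  if (anyDuplicated(tree$tip.label)) abort("Tree leaf labels are not unique.")
  tree
}
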