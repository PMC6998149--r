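test_that("construction from matrix and long data frame agree", {
  ft <- tiny_table()
  expect_s3_class(ft, "fmt_ftbl")
  expect_equal(sample_totals(ft)$total, c(6, 4))
  long <- data.frame(
    sample_id = rep(c("S1", "S2"), each = 3),
    taxon_id = rep(paste0("OTU", 1:3), 2),
    count = c(5, 0, 1, 0, 2, 2)
  )
  expect_equal(ft_matrix(feature_table(long)), ft_matrix(ft))
})

test_that("invalid counts are rejected with informative errors", {
  m <- matrix(c(1, -2), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(feature_table(m), "non-negative")
  m2 <- matrix(c(1.5, 2), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(feature_table(m2), "integral")
})

test_that("TSV round-trip preserves counts, ordering and taxonomy", {
  lin <- setNames(sprintf("k__Bacteria;p__X;g__G%d", 1:3), paste0("OTU", 1:3))
  ft <- feature_table(ft_matrix(tiny_table()) |> t(), lineage = lin)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  ft2 <- read_feature_table(path)
  expect_equal(ft_matrix(ft2), ft_matrix(ft))
  expect_equal(ft_sample_ids(ft2), ft_sample_ids(ft))
  expect_equal(ft_taxon_ids(ft2), ft_taxon_ids(ft))
  expect_equal(ft2$lineage, ft$lineage)
})

test_that("TSV parse errors name the offending column and line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tS1\tS2", "OTU1\t5\tx", "OTU2\t1\t2"), path)
  expect_error(read_feature_table(path), "S2.*line 1")
  writeLines(c("taxon_id\tS1", "OTU1\t-3"), path)
  expect_error(read_feature_table(path), "Negative")
})

test_that("BIOM-JSON sparse round-trip equals the TSV representation", {
  lin <- setNames(sprintf("k__B;p__P%d", 1:3), paste0("OTU", 1:3))
  ft <- feature_table(t(ft_matrix(tiny_table())), lineage = lin)
  biom_path <- withr::local_tempfile(fileext = ".biom")
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, biom_path)
  write_feature_table(ft, tsv_path)
  from_biom <- read_feature_table(biom_path)
  from_tsv <- read_feature_table(tsv_path)
  expect_equal(ft_matrix(from_biom), ft_matrix(from_tsv))
  expect_equal(from_biom$lineage, from_tsv$lineage)
  # independent reader: the Bioconductor BIOM parser sees the same counts
  skip_if_not_installed("biomformat")
  b <- biomformat::read_biom(biom_path)
  expect_equal(unname(as(biomformat::biom_data(b), "matrix")),
               unname(t(ft_matrix(ft))))
})

test_that("malformed BIOM input names the missing key", {
  path <- withr::local_tempfile(fileext = ".biom")
  writeLines('{"rows": [], "columns": []}', path)
  expect_error(read_feature_table(path), "data")
})

test_that("relative abundances sum to one and zero-total samples are named", {
  ft <- feature_table(matrix(c(1, 1, 2), 3, 1,
                             dimnames = list(paste0("t", 1:3), "S1")))
  expect_equal(relative_abundance(ft)$rel_abund, c(0.25, 0.25, 0.5))
  one <- feature_table(matrix(4, 1, 1, dimnames = list("t", "only")))
  expect_equal(relative_abundance(one)$rel_abund, 1)
  ft2 <- feature_table(matrix(c(3, 7), 2, 1, dimnames = list(c("a", "b"), "S1")))
  expect_equal(relative_abundance(ft2)$rel_abund, c(0.3, 0.7))
  m <- matrix(c(1, 3, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(relative_abundance(feature_table(m)), "empty")
  for (i in 1:5) {
    rt <- random_table(4, 12)
    sums <- relative_abundance(rt) |>
      dplyr::summarise(s = sum(rel_abund), .by = sample_id)
    expect_true(all(abs(sums$s - 1) < 1e-9))
  }
})

test_that("metadata validation enforces the trial schedule and donor rules", {
  md <- toy_metadata("P1", c(P1 = "FMT"), c("D0", "W6"))
  expect_s3_class(md, "tbl_df")
  bad_tp <- md; bad_tp$timepoint[1] <- "W99"
  expect_error(sample_metadata(bad_tp), "W99")
  bad_donor <- md; bad_donor$arm[bad_donor$role == "donor"] <- "FMT"
  expect_error(sample_metadata(bad_donor), "donor")
  expect_error(sample_metadata(md[, -1]), "sample_id")
})

test_that("the shipped synthetic demo cohort loads and is internally consistent", {
  tsv <- system.file("extdata", "demo_counts.tsv", package = "fmtengraft")
  biom <- system.file("extdata", "demo_counts.biom", package = "fmtengraft")
  md <- read_sample_metadata(system.file("extdata", "demo_metadata.tsv",
                                         package = "fmtengraft"))
  ft <- read_feature_table(tsv)
  expect_identical(ft_matrix(ft), ft_matrix(read_feature_table(biom)))
  expect_setequal(ft_sample_ids(ft), md$sample_id)
  tree <- read_phylogeny(system.file("extdata", "demo_tree.nwk",
                                     package = "fmtengraft"))
  expect_setequal(tree$tip.label, ft_taxon_ids(ft))
  d <- unweighted_unifrac(ft, tree)
  expect_true(all(d >= 0 & d <= 1))
})
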