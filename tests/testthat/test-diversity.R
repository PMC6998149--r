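test_that("shannon matches hand values and is maximal at evenness", {
  expect_equal(shannon(rep(5, 4)), 2)
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)), 1.5)
  expect_error(shannon(c(0, 0)), "zero")
  set.seed(11)
  for (i in 1:10) {
    x <- sample(1:30, 6, replace = TRUE)
    expect_lte(shannon(x), shannon(rep(1, 6)) + 1e-12)
  }
  # base switch: natural-log value agrees with vegan
  x <- c(4, 9, 1, 6)
  expect_equal(shannon(x, base = exp(1)),
               unname(vegan::diversity(x, index = "shannon")))
})

test_that("chao1 follows the classic / bias-corrected branch structure", {
  # S_obs = 10, F1 = 4, F2 = 2 -> 10 + 16/4 = 14 (classic)
  expect_equal(chao1(c(rep(1, 4), rep(2, 2), rep(7, 4))), 14)
  # no singletons -> S_obs
  expect_equal(chao1(c(3, 5, 2)), 3)
  # F1 = 3, F2 = 0, S_obs = 5 -> 5 + 3*2/2 = 8 (bias-corrected)
  expect_equal(chao1(c(1, 1, 1, 4, 5)), 8)
  expect_error(chao1(c(0.5, 1.5)), "integer")
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(40, 1.2)
    if (sum(x) == 0) next
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("bray-curtis matches hand arithmetic and metric axioms", {
  m <- matrix(c(2, 1, 0, 0, 1, 3), 3, 2,
              dimnames = list(paste0("t", 1:3), c("x", "y")))
  d <- bray_curtis(feature_table(m))
  # relative abundances (2/3, 1/3, 0) vs (0, 1/4, 3/4): sum|diff| = 3/2 -> 0.75
  expect_equal(d["x", "y"], 0.75)
  expect_equal(d["x", "y"], oracle_bray(m[, "x"], m[, "y"]))

  ident <- matrix(c(3, 1, 3, 1), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(bray_curtis(feature_table(ident))["s1", "s2"], 0)
  disj <- matrix(c(5, 0, 0, 9), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(bray_curtis(feature_table(disj))["s1", "s2"], 1)

  set.seed(3)
  for (i in 1:5) {
    rt <- random_table(5, 15)
    d <- bray_curtis(rt)
    expect_true(all(diag(d) == 0))
    expect_equal(unclass(d), t(unclass(d)))
    expect_true(all(d >= 0 & d <= 1))
    ra <- ft_matrix(rt)
    for (pair in list(c(1, 2), c(2, 5))) {
      expect_equal(d[pair[1], pair[2]],
                   oracle_bray(ra[pair[1], ], ra[pair[2], ]))
    }
  }
})

test_that("sorensen similarity is the exact complement of bray-curtis", {
  rt <- random_table(4, 10)
  d <- bray_curtis(rt)
  s <- sorensen_similarity(d)
  expect_equal(unclass(s), 1 - unclass(d), ignore_attr = TRUE)
  expect_true(all(diag(s) == 1))
  # the trial's lowest observed donor-recipient similarity: BC 0.88 -> S 0.12
  d88 <- matrix(c(0, 0.88, 0.88, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(sorensen_similarity(d88)["a", "b"], 0.12)
})

test_that("moving two samples apart in one taxon lowers their sorensen", {
  base <- c(10, 10, 10, 10)
  other <- c(10, 10, 10, 10)
  prev <- 1
  for (bump in c(0, 5, 15, 40)) {
    y <- other; y[1] <- y[1] + bump
    m <- matrix(c(base, y), 4, 2, dimnames = list(paste0("t", 1:4), c("a", "b")))
    s <- sorensen_similarity(bray_curtis(feature_table(m)))["a", "b"]
    expect_lte(s, prev + 1e-12)
    prev <- s
  }
})

test_that("unweighted unifrac matches the branch-enumeration oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  d <- unweighted_unifrac(feature_table(m), tree)
  expect_equal(d["s1", "s2"], oracle_unifrac(tree, c("A", "B"), c("A", "C")))
  expect_equal(d["s1", "s2"], 0.6)

  ident <- matrix(c(1, 1, 0, 0, 2, 3, 0, 0), 4, 2,
                  dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  expect_equal(unweighted_unifrac(feature_table(ident), tree)["s1", "s2"], 0)

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  disj <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  expect_equal(unweighted_unifrac(feature_table(disj), star)["s1", "s2"], 1)

  bad <- matrix(c(1, 1), 2, 1, dimnames = list(c("A", "Zmissing"), "s1"))
  expect_error(unweighted_unifrac(feature_table(bad), tree), "Zmissing")
})

test_that("alpha_diversity tabulates per-sample indices", {
  ft <- tiny_table()
  ad <- alpha_diversity(ft)
  expect_equal(ad$sample_id, c("S1", "S2"))
  expect_equal(ad$shannon[1], shannon(c(5, 0, 1)))
  expect_equal(ad$observed, c(2, 2))
})
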