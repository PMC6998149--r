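test_that("the endpoint classifier applies both conditions and the tie rule", {
  res <- classify_engraftment(data.frame(
    s_donor_w6 = c(0.65, 0.12, 0.70, NA),
    s_self_w6 = c(0.30, 0.05, 0.70, NA)
  ))
  expect_equal(res$success, c(TRUE, FALSE, FALSE, FALSE))
  # particularly low donor similarity fails on the threshold arm
  expect_false(res$threshold_pass[2])
  expect_true(res$comparative_pass[2])
  # exact tie fails the strict comparative condition
  expect_false(res$comparative_pass[3])
  # missing week-6 data is imputed as failure
  expect_true(res$missing_data[4])
  expect_false(res$success[4])
  expect_error(classify_engraftment(data.frame(s_donor_w6 = 1.4, s_self_w6 = 0.2)),
               "0, 1")
})

test_that("success is monotone in donor similarity", {
  grid <- seq(0, 1, by = 0.05)
  for (s_self in c(0.1, 0.55, 0.9)) {
    succ <- classify_engraftment(
      data.frame(s_donor_w6 = grid, s_self_w6 = s_self))$success
    expect_true(all(diff(succ) >= 0))  # never success -> failure as s_donor grows
  }
})

test_that("low-similarity failure flags reproduce the trial's two failures", {
  w6 <- data.frame(
    subject_id = paste0("F", 1:8),
    s_donor_w6 = c(0.12, 0.15, 0.29, 0.33, 0.41, 0.47, 0.52, 0.56)
  )
  out <- failure_by_low_similarity(w6, cut = 0.2)
  expect_equal(out$subject_id[out$low_similarity_failure], c("F1", "F2"))
  expect_false(any(failure_by_low_similarity(w6, cut = 0.1)$low_similarity_failure))
  expect_true(all(failure_by_low_similarity(w6, cut = 0.99)$low_similarity_failure))
  expect_error(failure_by_low_similarity(w6[0, ]), "non-empty")
})

test_that("engraftment similarities compare W6 to donor and to baseline", {
  # recipient W6 identical to donor, baseline disjoint: s_donor 1, s_self 0
  donor <- c(10, 10, 0, 0)
  base <- c(0, 0, 10, 10)
  m <- cbind(P1_D0 = base, P1_W6 = donor, DON1_donor = donor)
  rownames(m) <- paste0("t", 1:4)
  md <- toy_metadata("P1", c(P1 = "FMT"), c("D0", "W6"))
  sims <- engraftment_similarities(feature_table(m), md)
  expect_equal(sims$s_donor_w6, 1)
  expect_equal(sims$s_self_w6, 0)
  # subject with no W6 sample comes back as missing
  md2 <- toy_metadata("P1", c(P1 = "FMT"), c("D0", "W6"))
  m2 <- m[, c("P1_D0", "DON1_donor")]
  sims2 <- engraftment_similarities(feature_table(m2), md2)
  expect_true(sims2$missing_data)
})

test_that("trajectories use the assigned donor for FMT and the donor mean for sham", {
  donors <- list(DON1 = c(10, 0, 0), DON2 = c(0, 10, 0), DON3 = c(0, 0, 10))
  recip <- c(10, 0, 0)   # identical to DON1
  m <- cbind(P1_D0 = recip, P1_W6 = recip,
             DON1_donor = donors$DON1, DON2_donor = donors$DON2,
             DON3_donor = donors$DON3)
  rownames(m) <- paste0("t", 1:3)
  ft <- feature_table(m)

  md_fmt <- toy_metadata("P1", c(P1 = "FMT"), c("D0", "W6"),
                         donor_ids = c("DON1", "DON2", "DON3"))
  traj <- donor_similarity_trajectory(ft, md_fmt)
  expect_equal(traj$sorensen, c(1, 1))

  md_sham <- toy_metadata("P1", c(P1 = "sham"), c("D0", "W6"),
                          donor_ids = c("DON1", "DON2", "DON3"))
  traj_sham <- donor_similarity_trajectory(ft, md_sham)
  pair_sims <- vapply(donors, function(d) {
    sorensen_pair(recip, d)
  }, numeric(1))
  expect_equal(traj_sham$sorensen, rep(mean(pair_sims), 2))

  md_bad <- md_fmt
  md_bad$donor_id[md_bad$role == "recipient"] <- NA_character_
  expect_error(donor_similarity_trajectory(ft, md_bad), "donor_id")
})

test_that("new-OTU tracking measures abundance from taxa absent pre-intervention", {
  pre <- c(50, 50, 0)
  m <- cbind(`P1_W-2` = pre, P1_D0 = pre,
             P1_W6 = c(45, 45, 10),      # one new OTU at 10% of depth 100
             P1_W10 = pre,               # identical to baseline: 0
             P1_W14 = c(0, 0, 100))      # entirely new
  rownames(m) <- paste0("t", 1:3)
  md <- toy_metadata("P1", c(P1 = "FMT"), c("W-2", "D0", "W6", "W10", "W14"))
  ft <- feature_table(m)
  out <- track_new_otus(ft, md)
  expect_equal(out$new_otu_proportion[out$timepoint == "W6"], 0.10)
  expect_equal(out$new_otu_proportion[out$timepoint == "W10"], 0)
  expect_equal(out$new_otu_proportion[out$timepoint == "W14"], 1)

  # invariant to taxon relabeling
  m_perm <- m[c(3, 1, 2), ]
  rownames(m_perm) <- paste0("t", 1:3)
  out_perm <- track_new_otus(feature_table(m_perm), md)
  expect_equal(out_perm$new_otu_proportion, out$new_otu_proportion)

  md_nopre <- toy_metadata("P1", c(P1 = "FMT"), c("D0", "W6"))
  expect_error(track_new_otus(ft, md_nopre), "P1")
})
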