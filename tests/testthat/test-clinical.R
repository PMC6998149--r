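test_that("the flare rule fires on each clause and only those", {
  expect_true(is_flare(230, 100))                        # CDAI > 220
  expect_true(is_flare(180, 100))                        # 150-220 with rise > 70
  expect_false(is_flare(140, 60))
  expect_false(is_flare(180, 120))                       # rise of 60 only
  expect_true(is_flare(100, 100, new_treatment_or_surgery = TRUE))
  expect_equal(is_flare(c(230, 140), c(0, 0)), c(TRUE, FALSE))
  expect_error(is_flare(-5, 0), "non-negative")
})

test_that("remission rates follow the ITT and imputation rules", {
  fx <- trial_outcome_fixture()
  expect_equal(nrow(fx), 17)
  # an arm with zero flares scores 100%
  quiet <- data.frame(subject_id = c("a", "b"), arm = "FMT",
                      flare_after = NA_real_, flare_by = NA_real_,
                      dropout_week = NA_real_, dropout_in_remission = FALSE)
  expect_equal(remission_rate(quiet, "FMT", 10)$rate, 1)
  # 5 flares among 9 by the week -> 4/9
  expect_equal(remission_rate(fx, "sham", 10)$rate, 4 / 9)
  # week-24 imputation: the week-12 dropout-in-remission counts as flare
  r24 <- remission_rate(fx, "FMT", 24)
  expect_equal(r24$n_imputed, 1)
  expect_equal(r24$rate, 0.5)
  # conservation: remission + flares + imputed = arm size
  for (arm in c("FMT", "sham")) for (wk in c(10, 24)) {
    r <- remission_rate(fx, arm, wk)
    expect_equal(r$n_remission + r$n_flare + r$n_imputed, r$n_total)
  }
  expect_error(remission_rate(fx, "placebo", 10), "arm")
  expect_error(remission_rate(fx, "FMT", 12), "10 or 24")
})

test_that("fisher matches its published value and the enumeration oracle", {
  expect_equal(round(fisher_exact(matrix(c(6, 0, 4, 5), 2, byrow = TRUE))$p_value, 2),
               0.04)
  # no successes anywhere: p = 1
  expect_equal(fisher_exact(matrix(c(0, 8, 0, 9), 2, byrow = TRUE))$p_value, 1)
  # diagonal table against brute-force hypergeometric enumeration
  tab <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab))
  set.seed(2)
  for (i in 1:60) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact(matrix(0L, 2, 2)), "Empty")
})

test_that("rank-sum test: exact separation case and order invariance", {
  # fully separated 3v3: only 2 of the choose(6,3)=20 assignments are as extreme
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$p_value, 2 / 20)
  expect_equal(res$method, "exact")
  same <- wilcoxon_rank_sum(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(same$p_value, 0.9)
  a <- c(3, 9, 4, 7); b <- c(5, 1, 8, 2)
  expect_equal(wilcoxon_rank_sum(a, b)$statistic,
               wilcoxon_rank_sum(sample(a), sample(b))$statistic)
  expect_error(wilcoxon_rank_sum(1, c(2, 3)), ">= 2")
})

test_that("signed-rank test: constant shift, zero drop, and sign flip", {
  before <- c(10, 20, 30, 40, 50, 60)
  after <- before + c(1, 2, 3, 4, 5, 6)
  res <- wilcoxon_signed_rank(before, after)
  # all positive differences: the one-sided extreme; two-sided exact p = 2/2^6
  expect_equal(res$p_value, 2 / 2^6)
  expect_equal(res$n_pairs_used, 6)
  expect_error(wilcoxon_signed_rank(before, before), "non-zero")
  flipped <- wilcoxon_signed_rank(after, before)
  expect_equal(flipped$p_value, res$p_value)
  expect_equal(res$statistic + flipped$statistic, 6 * 7 / 2)  # V + V' = n(n+1)/2
  # zero differences are dropped, not ranked
  res_z <- wilcoxon_signed_rank(c(before, 7), c(after, 7))
  expect_equal(res_z$n_pairs_used, 6)
})

test_that("kaplan-meier equals hand product-limit values", {
  flat <- kaplan_meier(data.frame(time = c(4, 8, 24), event = FALSE))
  expect_true(all(tidy(flat)$survival == 1))
  one <- kaplan_meier(data.frame(time = c(2, 10, 10, 24), event = c(TRUE, FALSE, FALSE, FALSE)))
  expect_equal(min(tidy(one)$survival), 3 / 4)
  # 5-record toy with one censor at week 8
  rec <- data.frame(time = c(3, 5, 8, 14, 20),
                    event = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  km <- tidy(kaplan_meier(rec))
  hand <- oracle_km(rec$time, as.integer(rec$event))
  got <- km[km$n_event > 0, c("time", "survival")]
  expect_equal(as.data.frame(got), hand, ignore_attr = TRUE)
  # no censoring: product-limit equals the empirical survival function
  rec2 <- data.frame(time = c(1, 2, 2, 5, 9), event = TRUE)
  km2 <- tidy(kaplan_meier(rec2))
  emp <- vapply(km2$time, function(t) mean(rec2$time > t), numeric(1))
  expect_equal(km2$survival, emp)
  expect_error(kaplan_meier(data.frame(time = 0, event = TRUE)), "positive")
})

test_that("log-rank separates arms when and only when they differ", {
  same <- data.frame(time = rep(c(3, 6, 9, 24), 2),
                     event = rep(c(TRUE, TRUE, FALSE, FALSE), 2),
                     group = rep(c("A", "B"), each = 4))
  res_same <- log_rank(same)
  expect_lt(res_same$statistic, 1e-10)
  expect_equal(res_same$p_value, 1)
  early <- data.frame(time = c(2, 3, 4, 5, 20, 21, 22, 24),
                      event = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                      group = rep(c("A", "B"), each = 4))
  res <- log_rank(early)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$direction, "A")
  none <- data.frame(time = c(5, 6), event = FALSE, group = c("A", "B"))
  expect_error(log_rank(none), "No events")
})

test_that("log-rank p is approximately uniform under exchangeable arms", {
  set.seed(14)
  ps <- vapply(1:100, function(i) {
    time <- rexp(16, 0.1)
    rec <- data.frame(time = pmin(time, 24), event = time < 24,
                      group = rep(c("A", "B"), each = 8))
    if (sum(rec$event) == 0) return(NA_real_)
    log_rank(rec)$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(mean(ps < 0.5), 0.3)
  expect_lt(mean(ps < 0.5), 0.7)
  expect_lt(mean(ps < 0.1), 0.25)
})

test_that("the sample-size formula reproduces the trial design and is monotone", {
  trial <- sample_size_two_proportions(0.80, 0.005, alpha = 0.05, power = 0.90,
                                       attrition = 0.5)
  expect_equal(trial$n_inclusion_per_group, 12)
  expect_equal(trial$n_total_inclusion, 24)
  # zero attrition removes the inflation entirely
  no_attr <- sample_size_two_proportions(0.80, 0.005, alpha = 0.05, power = 0.90)
  expect_equal(no_attr$n_inclusion_per_group, no_attr$n_evaluable_per_group)
  expect_equal(trial$n_inclusion_per_group, 2 * no_attr$n_inclusion_per_group)
  # independently evaluated closed form: p1=0.75, p2=0.50, power 0.80 -> 58
  expect_equal(
    sample_size_two_proportions(0.75, 0.50, power = 0.80)$n_evaluable_per_group,
    58
  )
  # monotonicity in effect size and in power
  n_wide <- sample_size_two_proportions(0.8, 0.2)$n_evaluable_per_group
  n_narrow <- sample_size_two_proportions(0.8, 0.6)$n_evaluable_per_group
  expect_lte(n_wide, n_narrow)
  n_lo <- sample_size_two_proportions(0.7, 0.4, power = 0.8)$n_evaluable_per_group
  n_hi <- sample_size_two_proportions(0.7, 0.4, power = 0.95)$n_evaluable_per_group
  expect_gte(n_hi, n_lo)
  expect_error(sample_size_two_proportions(0.5, 0.5), "differ")
})

test_that("survival records refuse interval-only flares but accept exact weeks", {
  expect_error(as_survival_records(trial_outcome_fixture()), "refusing")
  rec <- data.frame(subject_id = c("a", "b", "c"), arm = "FMT",
                    flare_after = c(3, NA, NA), flare_by = c(4, NA, NA),
                    flare_week = c(4, NA, NA),
                    dropout_week = c(NA, 12, NA), dropout_in_remission = c(FALSE, TRUE, FALSE))
  sr <- as_survival_records(rec)
  expect_equal(sr$time, c(4, 12, 24))
  expect_equal(sr$event, c(TRUE, FALSE, FALSE))
})
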