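#' Clinical flare rule (CDAI-based)
#'
#' A flare is: CDAI above 220, or CDAI in [150, 220] with a rise of more than
#' 70 points over baseline, or the need for surgery / a new medical treatment
#' for the disease.
#'
#' @param cdai Current CDAI score(s), points.
#' @param cdai_baseline Baseline CDAI score(s), points.
#' @param new_treatment_or_surgery Logical flag(s).
#' @return Logical vector.
#' @examples
#' is_flare(230, 100)          # TRUE: first clause
#' is_flare(180, 100)          # TRUE: rise of 80 in the 150-220 band
#' is_flare(140, 60)           # FALSE
#' @export
is_flare <- function(cdai, cdai_baseline, new_treatment_or_surgery = FALSE) {
  if (any(cdai < 0, na.rm = TRUE) || any(cdai_baseline < 0, na.rm = TRUE)) {
    abort("CDAI scores must be non-negative.")
  }
  cdai > 220 |
    (cdai >= 150 & cdai <= 220 & (cdai - cdai_baseline) > 70) |
    as.logical(new_treatment_or_surgery)
}

#' Steroid-free clinical remission rate at a scheduled week
#'
#' Intention-to-treat remission proportion for one arm. A subject is in
#' remission at the week iff no flare interval closes at or before it. The
#' week-24 endpoint additionally imputes *flare* for subjects who dropped out
#' while in remission before week 24 (the trial's handling of its week-12
#' dropout); Kaplan-Meier input is deliberately *not* imputed this way — the
#' subject is censored there.
#'
#' @param records Outcome records: data frame with `subject_id`, `arm`, and
#'   interval-coded flares `flare_after` / `flare_by` (flare occurred in
#'   `(flare_after, flare_by]`; both NA means no flare), plus `dropout_week`
#'   and `dropout_in_remission` (see [trial_outcome_fixture()]).
#' @param arm `"FMT"` or `"sham"`.
#' @param week Endpoint week, 10 or 24.
#' @return One-row tibble: `arm`, `week`, `n_remission`, `n_flare`,
#'   `n_imputed`, `n_total`, `rate` (and `rate_percent`).
#' @export
remission_rate <- function(records, arm, week) {
  records <- validate_outcomes(records)
  if (!arm %in% records$arm) abort(sprintf("Unknown arm '%s'.", arm))
  if (!week %in% c(10, 24)) abort("`week` must be 10 or 24 (scheduled endpoints).")
  r <- filter(records, .data$arm == !!arm)
  flared <- !is.na(r$flare_by) & r$flare_by <= week
  imputed <- rep(FALSE, nrow(r))
  if (week == 24) {
    imputed <- !flared & r$dropout_in_remission & !is.na(r$dropout_week) &
      r$dropout_week < 24
  }
  n_rem <- sum(!flared & !imputed)
  tibble(
    arm = arm, week = week,
    n_remission = n_rem,
    n_flare = sum(flared),
    n_imputed = sum(imputed),
    n_total = nrow(r),
    rate = n_rem / nrow(r),
    rate_percent = 100 * n_rem / nrow(r)
  )
}

validate_outcomes <- function(records) {
  need <- c("subject_id", "arm", "flare_after", "flare_by",
            "dropout_week", "dropout_in_remission")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(sprintf("Outcome records lack column(s): %s", paste(miss, collapse = ", ")))
  }
  r <- as_tibble(records)
  if (nrow(r) == 0) abort("Outcome records are empty.")
  bad <- !is.na(r$flare_by) & (r$flare_by < 0 | r$flare_by > 24)
  if (any(bad)) abort("flare_by weeks must lie within [0, 24].")
  if (any(!is.na(r$dropout_week) & r$dropout_week > 24)) {
    abort("dropout_week must be <= 24.")
  }
  r
}

#' Fisher's exact test (two-sided) on a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables (at fixed margins) no more
#' probable than the observed one — the convention under which the trial's
#' engraftment-success vs sham remission contrast gives p = 0.04. Thin,
#' validating wrapper over [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row tibble: `p_value`, `odds_ratio`.
#' @examples
#' fisher_exact(matrix(c(6, 0, 4, 5), 2, byrow = TRUE))  # p = 0.04
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2, 2))) {
    abort("`table` must be a 2x2 matrix.")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(table) == 0) {
    abort("Empty table: all margins are zero, the test is undefined.")
  }
  ft <- fisher.test(table, alternative = "two.sided")
  tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value for combined n <= 20 without ties; tie-corrected normal
#' approximation otherwise. The method actually used is reported.
#'
#' @param x,y Numeric score vectors, each with >= 2 observations.
#' @return One-row tibble: `statistic` (W), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("Each group needs >= 2 observations.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  fit <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  tibble(
    statistic = unname(fit$statistic),
    p_value = fit$p.value,
    method = if (exact) "exact" else "normal approximation, tie-corrected"
  )
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Zero differences are dropped before ranking (Wilcoxon's original
#' convention); exact p for up to 15 informative pairs without tied absolute
#' differences.
#'
#' @param before,after Paired numeric vectors of equal length.
#' @return One-row tibble: `statistic` (V, on `after - before`), `p_value`,
#'   `n_pairs_used`, `method`.
#' @export
wilcoxon_signed_rank <- function(before, after) {
  if (length(before) != length(after)) abort("`before` and `after` must be paired.")
  d <- after - before
  d <- d[d != 0]
  if (length(d) < 2) {
    abort("Fewer than 2 non-zero differences; the signed-rank test is undefined.")
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 15 && !ties
  fit <- suppressWarnings(wilcox.test(after, before, paired = TRUE,
                                      exact = exact, correct = !exact))
  tibble(
    statistic = unname(fit$statistic),
    p_value = fit$p.value,
    n_pairs_used = length(d),
    method = if (exact) "exact" else "normal approximation, tie-corrected"
  )
}

#' Kaplan-Meier remission curve
#'
#' Product-limit estimate of the probability of remaining in remission, from
#' per-subject time-to-flare records. Dropouts are censored at last contact;
#' the week-24 dropout-as-flare imputation applies only to the week-24
#' remission *rate*, never here.
#'
#' @param records Data frame with `time` (weeks, > 0) and `event` (logical or
#'   0/1; TRUE = flare).
#' @return A `fmt_km` object wrapping [survival::survfit()]; `tidy()` gives
#'   the step function (`time`, `n_risk`, `n_event`, `n_censor`, `survival`).
#' @export
kaplan_meier <- function(records) {
  records <- as_tibble(records)
  if (!all(c("time", "event") %in% names(records)) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame with time and event columns.")
  }
  if (any(records$time <= 0)) abort("Survival times must be positive.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = mutate(records, event = as.integer(.data$event)))
  structure(list(fit = fit, n = nrow(records)), class = "fmt_km")
}

#' @export
print.fmt_km <- function(x, ...) {
  print(x$fit, ...)
  invisible(x)
}

#' @describeIn kaplan_meier The estimated step function as a tibble.
#' @param x A `fmt_km` object.
#' @param ... Unused.
#' @method tidy fmt_km
#' @export
tidy.fmt_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv
  )
}

#' @describeIn kaplan_meier Step plot of the remission probability.
#' @param object A `fmt_km` object.
#' @method autoplot fmt_km
#' @export
autoplot.fmt_km <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, survival = 1), tidy(object)[c("time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "weeks", y = "probability of remaining in remission") +
    ggplot2::theme_minimal()
}

#' Log-rank test comparing time-to-flare between arms
#'
#' Standard log-rank with hypergeometric variance at each event time, via
#' [survival::survdiff()].
#'
#' @param records Data frame with `time`, `event`, and `group` columns
#'   (exactly two groups; at least one event overall).
#' @return One-row tibble: `statistic` (chi-square, 1 df), `p_value`, and
#'   `direction` (which group flared more than expected).
#' @export
log_rank <- function(records) {
  records <- as_tibble(records)
  need <- c("time", "event", "group")
  if (!all(need %in% names(records))) {
    abort("`records` must have time, event and group columns.")
  }
  if (any(records$time <= 0)) abort("Survival times must be positive.")
  if (sum(records$event) == 0) abort("No events: the log-rank test is undefined.")
  records$event <- as.integer(records$event)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  groups <- sub("^group=", "", names(fit$n))
  excess <- fit$obs - fit$exp
  tibble(
    statistic = unname(fit$chisq),
    p_value = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
    direction = groups[which.max(excess)]
  )
}

#' Two-proportion sample-size calculation
#'
#' Normal-approximation sample size for detecting `p1` vs `p2` with a
#' two-sided test: pooled variance under the null, unpooled under the
#' alternative, no continuity correction by default (the variant under which
#' the trial's design parameters - 80% vs 0.5%, alpha 5%, power 90%, 50%
#' attrition - give 24 patients total). Evaluable n per group is rounded up;
#' inclusion n inflates by `1 / (1 - attrition)` and is rounded up again.
#'
#' @param p1,p2 Success proportions under the alternative (must differ).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power, `1 - beta` (default 0.90).
#' @param attrition Anticipated non-evaluable fraction in `[0, 1)`.
#' @param continuity_correction Apply the Fleiss continuity correction to the
#'   evaluable n (default FALSE; not used for the trial's calculation).
#' @return One-row tibble: `n_evaluable_per_group`, `n_inclusion_per_group`,
#'   `n_total_inclusion`.
#' @examples
#' sample_size_two_proportions(0.80, 0.005, alpha = 0.05, power = 0.90,
#'                             attrition = 0.5)
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.90,
                                        attrition = 0,
                                        continuity_correction = FALSE) {
  for (v in c(p1, p2, alpha, power)) {
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      abort("p1, p2, alpha and power must all lie in (0, 1).")
    }
  }
  if (p1 == p2) abort("p1 and p2 must differ.")
  if (attrition < 0 || attrition >= 1) abort("`attrition` must be in [0, 1).")

  pbar <- (p1 + p2) / 2
  z_a <- qnorm(1 - alpha / 2)
  z_b <- qnorm(power)
  num <- (z_a * sqrt(2 * pbar * (1 - pbar)) +
            z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2
  n <- num / (p1 - p2)^2
  if (continuity_correction) {
    n <- n / 4 * (1 + sqrt(1 + 4 / (n * abs(p1 - p2))))^2
  }
  n_eval <- ceiling(n)
  n_incl <- ceiling(n_eval / (1 - attrition))
  tibble(
    n_evaluable_per_group = n_eval,
    n_inclusion_per_group = n_incl,
    n_total_inclusion = 2 * n_incl
  )
}
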