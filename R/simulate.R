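#' Configuration for the synthetic FMT cohort simulator
#'
#' The simulator emulates the longitudinal structure the engraftment analysis
#' assumes: sparse donor and recipient baseline communities drawn from
#' Dirichlet distributions, post-intervention samples drawn as multinomial
#' counts from the linear compositional mixture
#' `lambda * donor + (1 - lambda) * baseline` with per-timepoint
#' logistic-normal drift, and clinical flares linked to engraftment through a
#' logistic model `P(flare by W24) = plogis(b0 - b1 * lambda)`. Sham subjects
#' have `lambda = 0` by construction.
#'
#' @param n_fmt,n_sham Arm sizes (defaults 8 and 9, the trial's ITT arms).
#' @param n_donors Number of study donors (default 3).
#' @param n_taxa Taxa in the simulated community (default 150).
#' @param depth Nominal reads per sample (default 29000, the rarefaction
#'   depth); actual library sizes are drawn in `depth * depth_range` so that
#'   rarefaction has work to do.
#' @param depth_range Multiplicative range of library sizes (default
#'   `c(1, 1.3)`).
#' @param donor_concentration,recipient_concentration Dirichlet concentration
#'   parameters (default 0.3: sparse, realistically uneven 16S profiles with
#'   partially overlapping dominant taxa between communities).
#' @param lambda_distribution Function of `n` returning per-patient
#'   engraftment coefficients in `[0, 1]` (default `runif(n, 0.3, 0.9)`).
#' @param flare_link Numeric `c(b0, b1)` of the logistic flare link (default
#'   `c(0.7, 2.5)`: a sham-arm flare probability near the trial's 6/9, falling
#'   with engraftment).
#' @param noise_sd Standard deviation of the per-timepoint log-normal
#'   compositional drift (default 0.4).
#' @param seed Integer seed; the whole cohort is deterministic under it.
#' @return A validated `fmt_simconfig` list.
#' @export
simulation_config <- function(n_fmt = 8, n_sham = 9, n_donors = 3,
                              n_taxa = 150, depth = 29000,
                              depth_range = c(1, 1.3),
                              donor_concentration = 0.3,
                              recipient_concentration = 0.3,
                              lambda_distribution = function(n) runif(n, 0.3, 0.9),
                              flare_link = c(b0 = 0.7, b1 = 2.5),
                              noise_sd = 0.4,
                              seed = 1L) {
  cfg <- list(
    n_fmt = n_fmt, n_sham = n_sham, n_donors = n_donors, n_taxa = n_taxa,
    depth = depth, depth_range = depth_range,
    donor_concentration = donor_concentration,
    recipient_concentration = recipient_concentration,
    lambda_distribution = lambda_distribution,
    flare_link = flare_link, noise_sd = noise_sd, seed = seed
  )
  problems <- character()
  for (f in c("n_fmt", "n_sham", "n_donors", "n_taxa", "depth")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      problems <- c(problems, sprintf("%s must be an integer >= 1", f))
    }
  }
  for (f in c("donor_concentration", "recipient_concentration", "noise_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      problems <- c(problems, sprintf("%s must be non-negative", f))
    }
  }
  if (!is.function(cfg$lambda_distribution)) {
    problems <- c(problems, "lambda_distribution must be a function(n)")
  }
  if (!is.numeric(cfg$flare_link) || length(cfg$flare_link) != 2) {
    problems <- c(problems, "flare_link must be numeric c(b0, b1)")
  }
  if (length(problems)) {
    abort(paste0("Invalid simulation config:\n", paste("-", problems, collapse = "\n")))
  }
  structure(cfg, class = "fmt_simconfig")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[sample.int(length(x), 1)] <- 1
  x / sum(x)
}

drift <- function(p, sd) {
  if (sd == 0) return(p)
  q <- p * exp(stats::rnorm(length(p), 0, sd))
  q / sum(q)
}

#' Simulate a longitudinal FMT trial cohort
#'
#' Generates donor samples, recipient samples at every scheduled visit (W-2,
#' D0, then W2-W24), per-patient true engraftment coefficients, and clinical
#' outcomes, under [simulation_config()]. The per-patient engraftment
#' coefficient `lambda` mixes the assigned donor profile into the subject's
#' baseline for all post-intervention timepoints; flares (with an exact flare
#' week, uniform over weeks 1-24) follow the logistic link in `lambda`.
#'
#' @param cfg A [simulation_config()].
#' @return A `fmt_cohort` list: `table` (feature table), `metadata`
#'   (sample metadata), `truth` (tibble `subject_id`, `arm`, `donor_id`,
#'   `lambda`), `outcomes` (interval- and exact-week-coded flare records),
#'   and `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "fmt_simconfig")) cfg <- do.call(simulation_config, cfg)
  with_seed(cfg$seed, {
    k <- cfg$n_taxa
    taxa <- sprintf("OTU%03d", seq_len(k))
    donor_ids <- sprintf("DON%d", seq_len(cfg$n_donors))
    donor_prof <- t(vapply(seq_len(cfg$n_donors),
                           function(i) rdirichlet1(rep(cfg$donor_concentration, k)),
                           numeric(k)))

    subjects <- tibble(
      subject_id = sprintf("P%02d", seq_len(cfg$n_fmt + cfg$n_sham)),
      arm = c(rep("FMT", cfg$n_fmt), rep("sham", cfg$n_sham))
    )
    subjects$donor_id <- ifelse(
      subjects$arm == "FMT",
      donor_ids[(seq_len(nrow(subjects)) - 1L) %% cfg$n_donors + 1L],
      NA_character_
    )
    lam <- cfg$lambda_distribution(cfg$n_fmt)
    if (any(lam < 0 | lam > 1)) abort("lambda_distribution produced values outside [0, 1].")
    subjects$lambda <- ifelse(subjects$arm == "FMT", lam, 0)

    draw <- function(prof) {
      size <- round(cfg$depth * runif(1, cfg$depth_range[1], cfg$depth_range[2]))
      as.integer(rmultinom(1, size, prof))
    }

    counts <- list()
    meta <- list()
    for (i in seq_len(cfg$n_donors)) {
      sid <- paste0(donor_ids[i], "_donor")
      counts[[sid]] <- draw(drift(donor_prof[i, ], cfg$noise_sd))
      meta[[sid]] <- tibble(sample_id = sid, subject_id = donor_ids[i],
                            role = "donor", arm = "none", timepoint = "donor",
                            donor_id = NA_character_)
    }
    recipient_tps <- setdiff(TIMEPOINTS, "donor")
    for (j in seq_len(nrow(subjects))) {
      base <- rdirichlet1(rep(cfg$recipient_concentration, k))
      dprof <- if (subjects$arm[j] == "FMT") {
        donor_prof[match(subjects$donor_id[j], donor_ids), ]
      } else {
        rep(0, k)
      }
      lam_j <- subjects$lambda[j]
      for (tp in recipient_tps) {
        prof <- if (tp %in% c("W-2", "D0")) base else lam_j * dprof + (1 - lam_j) * base
        sid <- paste0(subjects$subject_id[j], "_", tp)
        counts[[sid]] <- draw(drift(prof, cfg$noise_sd))
        meta[[sid]] <- tibble(sample_id = sid, subject_id = subjects$subject_id[j],
                              role = "recipient", arm = subjects$arm[j],
                              timepoint = tp, donor_id = subjects$donor_id[j])
      }
    }

    m <- do.call(cbind, counts)
    rownames(m) <- taxa
    lineage <- setNames(sprintf("k__Bacteria;p__P%d;c__C%d;o__O%d;f__F%d;g__G%03d",
                                seq_len(k) %% 7 + 1, seq_len(k) %% 13 + 1,
                                seq_len(k) %% 17 + 1, seq_len(k) %% 29 + 1,
                                seq_len(k)),
                        taxa)
    table <- feature_table(m, lineage = lineage)
    metadata <- sample_metadata(bind_rows(meta))

    p_flare <- stats::plogis(cfg$flare_link[1] - cfg$flare_link[2] * subjects$lambda)
    flared <- rbinom(nrow(subjects), 1, p_flare) == 1
    flare_week <- ifelse(flared, sample(1:24, nrow(subjects), replace = TRUE), NA)
    outcomes <- tibble(
      subject_id = subjects$subject_id,
      arm = subjects$arm,
      flare_week = flare_week,
      flare_after = ifelse(flared, flare_week - 1, NA),
      flare_by = flare_week,
      dropout_week = NA_real_,
      dropout_in_remission = FALSE
    )

    structure(
      list(table = table, metadata = metadata,
           truth = select(subjects, "subject_id", "arm", "donor_id", "lambda"),
           outcomes = outcomes, config = cfg),
      class = "fmt_cohort"
    )
  })
}

#' @export
print.fmt_cohort <- function(x, ...) {
  cat(sprintf(
    "# Synthetic FMT cohort: %d FMT + %d sham recipients, %d donors, %d taxa, seed %s\n",
    x$config$n_fmt, x$config$n_sham, x$config$n_donors, x$config$n_taxa,
    format(x$config$seed)
  ))
  invisible(x)
}

#' In-trial clinical outcome records
#'
#' The 17 intention-to-treat outcome records of the trial (9 sham, 8 FMT),
#' interval-coded to be simultaneously consistent with all four published
#' steroid-free remission rates: sham 44.4% (4/9) at week 10 and 33.3% (3/9)
#' at week 24; FMT 87.5% (7/8) at week 10 and 50.0% (4/8) at week 24, the
#' latter counting the subject who dropped out in remission at week 12 as a
#' flare. Exact flare weeks were not published, so flares carry only the
#' interval `(flare_after, flare_by]`; operations needing exact weeks (such
#' as Kaplan-Meier) must refuse these records rather than fabricate times.
#'
#' @return Tibble of 17 outcome records (columns as in [remission_rate()]).
#' @export
trial_outcome_fixture <- function() {
  out <- bind_rows(
    # sham: 5 flares by W10, one more in (W10, W24], 3 remain in remission
    tibble(subject_id = sprintf("S%d", 1:5), arm = "sham",
           flare_after = 0, flare_by = 10),
    tibble(subject_id = "S6", arm = "sham", flare_after = 10, flare_by = 24),
    tibble(subject_id = sprintf("S%d", 7:9), arm = "sham",
           flare_after = NA_real_, flare_by = NA_real_),
    # FMT: 1 flare by W10, 2 more in (W10, W24], 1 dropout in remission at W12
    tibble(subject_id = "F1", arm = "FMT", flare_after = 0, flare_by = 10),
    tibble(subject_id = sprintf("F%d", 2:3), arm = "FMT",
           flare_after = 10, flare_by = 24),
    tibble(subject_id = "F4", arm = "FMT", flare_after = NA_real_,
           flare_by = NA_real_, dropout_week = 12, dropout_in_remission = TRUE),
    tibble(subject_id = sprintf("F%d", 5:8), arm = "FMT",
           flare_after = NA_real_, flare_by = NA_real_)
  )
  out$flare_week <- NA_real_   # exact weeks were never published
  out$dropout_in_remission[is.na(out$dropout_in_remission)] <- FALSE
  select(out, "subject_id", "arm", "flare_after", "flare_by", "flare_week",
         "dropout_week", "dropout_in_remission")
}

#' Engraftment success rates over simulated replicates
#'
#' Runs the full analysis pipeline (rarefy, Bray-Curtis, Sorensen,
#' classify) on `n_reps` independently simulated cohorts and tabulates the
#' engraftment-success proportion per arm with exact binomial Monte-Carlo
#' confidence intervals. Used to map where in (lambda, noise) space the
#' design assumption of a high FMT-arm success rate is attainable.
#'
#' @param cfg A [simulation_config()] (its seed is ignored here).
#' @param n_reps Number of replicate cohorts (>= 1).
#' @param seed Seed from which per-replicate seeds are derived.
#' @param threshold Endpoint similarity threshold (default 0.6).
#' @return Tibble: `arm`, `n_subjects`, `n_success`, `success_rate`,
#'   `ci_lower`, `ci_upper`.
#' @export
engraftment_power_experiment <- function(cfg = simulation_config(), n_reps = 20,
                                         seed = 1, threshold = 0.6) {
  if (!is.numeric(n_reps) || n_reps < 1) abort("`n_reps` must be >= 1.")
  calls <- purrr::map(seq_len(n_reps), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- (seed + 104729 * r) %% .Machine$integer.max
    co <- simulate_cohort(cfg_r)
    rf <- suppressMessages(rarefy_table(co$table, depth = cfg$depth,
                                        seed = cfg_r$seed))
    engraftment_similarities(rf, co$metadata) |>
      classify_engraftment(threshold = threshold)
  }) |> bind_rows()

  calls |>
    group_by(.data$arm) |>
    summarise(n_subjects = n(), n_success = sum(.data$success), .groups = "drop") |>
    mutate(
      success_rate = .data$n_success / .data$n_subjects,
      ci_lower = ifelse(.data$n_success == 0, 0,
                        stats::qbeta(0.025, .data$n_success + 0.5,
                                     .data$n_subjects - .data$n_success + 0.5)),
      ci_upper = ifelse(.data$n_success == .data$n_subjects, 1,
                        stats::qbeta(0.975, .data$n_success + 0.5,
                                     .data$n_subjects - .data$n_success + 0.5))
    )
}
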