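#' Default pipeline configuration
#'
#' A declarative configuration for [run_pipeline()]: either a `simulate` block
#' (arguments of [simulation_config()]) or an `input` block (`table`,
#' `metadata`, optional `outcomes` file paths), plus per-stage settings. All
#' stochastic stages draw their seeds from the single top-level `seed`.
#'
#' @param seed Top-level integer seed.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(),                    # defaults of simulation_config()
    rarefaction = list(depth = 29000),
    diversity = list(shannon_base = 2, anosim_permutations = 999,
                     anosim_timepoint = "W6"),
    engraftment = list(threshold = 0.6, low_similarity_cut = 0.2,
                       source_timepoints = c("W2", "W6")),
    differential = list(level = "genus", alpha = 0.05, score_threshold = 2,
                        grouping = "flare", timepoint = "W6"),
    clinical = list(weeks = c(10, 24))
  )
}

#' Run the full engraftment analysis pipeline
#'
#' Orchestrates load/simulate, rarefaction, alpha/beta diversity, PCoA,
#' ANOSIM, the engraftment endpoint, donor-similarity trajectories, new-OTU
#' tracking, source-mixture attribution, the differential-taxa screen, and
#' the clinical endpoint report. Every number in the reports is produced by
#' one exported function of this package; the orchestrator only wires stages
#' together. A stage that fails raises an error naming the stage; outputs of
#' completed stages are still written.
#'
#' Identical configuration (including seed) yields byte-identical reports.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file holding one.
#' @param output_dir Optional directory; when given, all reports are written
#'   as TSV/JSON together with `manifest.json`.
#' @return Invisibly, a named list of result tibbles plus `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_pipeline_config(), config)
  if (!is.null(config$simulate) && !is.null(config$input)) {
    abort("Config must request either 'simulate' or 'input', not both.")
  }
  seed <- cfg$seed %||% 1
  results <- list()
  if (!is.null(output_dir)) dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(output_dir)) write_bundle(results, output_dir)
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  # -- load / simulate --------------------------------------------------------
  data <- stage("load", {
    if (!is.null(config$input)) {
      inp <- config$input
      list(
        table = read_feature_table(inp$table),
        metadata = read_sample_metadata(inp$metadata),
        outcomes = if (!is.null(inp$outcomes)) {
          as_tibble(readr::read_tsv(inp$outcomes, show_col_types = FALSE))
        },
        truth = NULL
      )
    } else {
      sim_args <- cfg$simulate %||% list()
      if (identical(sim_args$lambda, "zero")) {
        sim_args$lambda_distribution <- function(n) rep(0, n)
        sim_args$lambda <- NULL
      }
      sim_args$seed <- sim_args$seed %||% seed
      co <- simulate_cohort(do.call(simulation_config, sim_args))
      list(table = co$table, metadata = co$metadata,
           outcomes = co$outcomes, truth = co$truth)
    }
  })
  if (identical(config$outcomes, "trial_fixture")) {
    data$outcomes <- trial_outcome_fixture()
  }

  # -- rarefaction ------------------------------------------------------------
  rarefied <- stage("rarefaction", {
    suppressMessages(rarefy_table(data$table, depth = cfg$rarefaction$depth,
                                  seed = seed))
  })
  results$rarefaction_dropped <- dropped_samples(rarefied)

  # -- diversity --------------------------------------------------------------
  stage("diversity", {
    results$alpha_diversity <- alpha_diversity(rarefied,
                                               base = cfg$diversity$shannon_base)
    bc <- bray_curtis(rarefied)
    results$sorensen <- tidy(sorensen_similarity(bc))
    ord <- pcoa(bc)
    results$pcoa_coordinates <- tidy(ord)
    results$pcoa_eigenvalues <- tibble(axis = seq_along(ord$eigenvalues),
                                       eigenvalue = ord$eigenvalues)
    md <- data$metadata
    tp <- cfg$diversity$anosim_timepoint
    w6 <- filter(md, .data$role == "recipient", .data$timepoint == tp,
                 .data$sample_id %in% rownames(bc))
    if (length(unique(w6$arm)) == 2 && all(table(w6$arm) >= 2)) {
      sub <- unclass(bc)[w6$sample_id, w6$sample_id]
      an <- anosim_test(new_dist_matrix(sub, attr(bc, "metric")),
                        setNames(w6$arm, w6$sample_id),
                        n_perm = cfg$diversity$anosim_permutations, seed = seed)
      results$anosim <- tidy(an)
    }
    invisible(NULL)
  })

  # -- engraftment ------------------------------------------------------------
  stage("engraftment", {
    sims <- engraftment_similarities(rarefied, data$metadata)
    results$engraftment <- classify_engraftment(sims,
                                                threshold = cfg$engraftment$threshold) |>
      failure_by_low_similarity(cut = cfg$engraftment$low_similarity_cut)
    results$trajectory <- donor_similarity_trajectory(rarefied, data$metadata)
    ok_subjects <- data$metadata |>
      filter(.data$role == "recipient",
             .data$sample_id %in% ft_sample_ids(rarefied)) |>
      group_by(.data$subject_id) |>
      summarise(ok = all(c("W-2", "D0") %in% .data$timepoint) &&
                  any(.data$timepoint %in% POST_TIMEPOINTS), .groups = "drop") |>
      filter(.data$ok) |>
      pull("subject_id")
    if (length(ok_subjects)) {
      results$new_otus <- track_new_otus(rarefied, data$metadata, ok_subjects)
    }
    results$source_mixture <- source_mixture_table(
      rarefied, data$metadata, timepoints = cfg$engraftment$source_timepoints)
    invisible(NULL)
  })

  # -- differential -----------------------------------------------------------
  if (!is.null(cfg$differential)) {
    stage("differential", {
      dcfg <- cfg$differential
      md <- filter(data$metadata, .data$role == "recipient",
                   .data$timepoint == dcfg$timepoint,
                   .data$sample_id %in% ft_sample_ids(rarefied))
      groups <- if (identical(dcfg$grouping, "flare") && !is.null(data$outcomes)) {
        fl <- !is.na(data$outcomes$flare_by)
        setNames(ifelse(fl, "flare", "no_flare"),
                 data$outcomes$subject_id)[md$subject_id]
      } else {
        md$arm
      }
      names(groups) <- md$sample_id
      keep <- !is.na(groups)
      sub <- ft_matrix(rarefied)[md$sample_id[keep], , drop = FALSE]
      if (length(unique(groups[keep])) == 2 && all(table(groups[keep]) >= 2)) {
        ft_sub <- feature_table(t(sub), lineage = lineage_map(rarefied))
        coll <- collapse_taxonomy(ft_sub, level = dcfg$level)
        results$differential_taxa <- differential_taxa(
          coll, groups[keep], alpha = dcfg$alpha,
          score_threshold = dcfg$score_threshold)
      }
      invisible(NULL)
    })
  }

  # -- clinical endpoints -----------------------------------------------------
  if (!is.null(data$outcomes)) {
    stage("clinical", {
      arms <- unique(data$outcomes$arm)
      grid <- tidyr::expand_grid(arm = arms, week = cfg$clinical$weeks)
      results$clinical_endpoints <- purrr::pmap(grid, function(arm, week) {
        remission_rate(data$outcomes, arm, week)
      }) |> bind_rows()
      if (length(arms) == 2) {
        results$remission_tests <- purrr::map(cfg$clinical$weeks, function(week) {
          rr <- purrr::map(arms, ~ remission_rate(data$outcomes, .x, week)) |> bind_rows()
          tab <- rbind(rr$n_remission, rr$n_total - rr$n_remission)
          bind_cols(tibble(week = week,
                           contrast = paste(arms, collapse = " vs ")),
                    fisher_exact(tab))
        }) |> bind_rows()
      }
      survrec <- tryCatch(as_survival_records(data$outcomes), error = function(e) NULL)
      if (!is.null(survrec) && sum(survrec$event) > 0) {
        results$kaplan_meier <- survrec |>
          group_by(.data$group) |>
          dplyr::group_modify(~ tidy(kaplan_meier(.x))) |>
          ungroup()
        if (length(unique(survrec$group)) == 2) {
          results$log_rank <- log_rank(survrec)
        }
      }
      invisible(NULL)
    })
  }

  results$manifest <- list(
    package_version = as.character(packageVersion("fmtengraft")),
    config_hash = rlang::hash(cfg),
    seed = seed,
    rarefaction_depth = cfg$rarefaction$depth,
    shannon_log_base = cfg$diversity$shannon_base,
    similarity_basis = "relative abundances of the rarefied table",
    fisher_convention = "two-sided, probability-mass (stats::fisher.test)",
    engraftment_threshold = cfg$engraftment$threshold,
    low_similarity_cut = cfg$engraftment$low_similarity_cut,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(output_dir)) write_bundle(results, output_dir)
  invisible(results)
}

lineage_map <- function(table) {
  if (!"lineage" %in% names(table)) return(NULL)
  d <- distinct(table, .data$taxon_id, .data$lineage)
  setNames(d$lineage, d$taxon_id)
}

write_bundle <- function(results, output_dir) {
  for (nm in setdiff(names(results), "manifest")) {
    obj <- results[[nm]]
    if (is.data.frame(obj)) {
      readr::write_tsv(obj, file.path(output_dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  if (!is.null(results$manifest)) {
    jsonlite::write_json(results$manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(output_dir)
}
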