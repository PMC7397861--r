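#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: either paths to existing
#' canonical CSVs or settings for simulating a cohort on the fly, the
#' stages to execute, sampler settings, and the output directory. All
#' randomness derives from the single `seed` via fixed offsets per stage
#' (simulation uses `seed`, MCMC `seed + 101`, the posterior predictive
#' check `seed + 202`).
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param stages Stages to run, a subset of `"simulate"`, `"preprocess"`,
#'   `"stats"`, `"lmm"`, `"fit"`, `"compare"`, `"ppc"`, `"associate"`,
#'   `"recover"`. Later stages require their inputs.
#' @param n_participants Cohort size when simulating.
#' @param task A [task_config()].
#' @param cohort A [cohort_settings()] list.
#' @param variants Observer variants to fit (subset of `"m1"`, `"m2"`,
#'   `"m3"`).
#' @param sampler Named list of sampler settings passed to
#'   [fit_observer()] (`chains`, `draws`, `warmup`, `adapt`, `thin`).
#' @param trials_csv,participants_csv,truth_json Input paths used when
#'   `"simulate"` is not among the stages (`truth_json` optional; required
#'   for the `"recover"` stage).
#' @param n_ppc_rep Posterior-predictive replicates.
#' @return A list of class `ap_run_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("actionprior_run_"),
                            seed = 1L,
                            stages = c("simulate", "preprocess", "stats",
                                       "lmm", "fit", "compare", "ppc",
                                       "associate", "recover"),
                            n_participants = 12,
                            task = task_config(blocks_per_condition = 2,
                                               n_blocks = 8,
                                               estimation_per_block = 10,
                                               basic_per_block = 17),
                            cohort = cohort_settings(),
                            variants = c("m1", "m2", "m3"),
                            sampler = list(chains = 2, draws = 250,
                                           warmup = 500, adapt = 500,
                                           thin = 4),
                            trials_csv = NULL, participants_csv = NULL,
                            truth_json = NULL,
                            n_ppc_rep = 100) {
  known <- c("simulate", "preprocess", "stats", "lmm", "fit", "compare",
             "ppc", "associate", "recover")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  }
  if (!("simulate" %in% stages) && length(stages) > 0 &&
      any(stages != "simulate")) {
    if (is.null(trials_csv) && length(setdiff(stages, "simulate")) > 0) {
      stop("without the simulate stage, trials_csv must be given",
           call. = FALSE)
    }
  }
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "ap_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or CSV loading), preprocessing,
#' performance ANOVAs, weighting-model selection, observer-model fits,
#' WAIC comparison, posterior predictive check, trait association, and
#' parameter-recovery scoring. Every artifact is written under
#' `config$out_dir` together with a JSON report carrying provenance (seed,
#' configuration hash, package version).
#'
#' @param config An [pipeline_config()] object.
#' @param quiet Suppress progress messages.
#' @return The report, invisibly (a list; also written as `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "ap_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  res <- list()
  on <- function(stage) stage %in% config$stages

  trials <- NULL; participants <- NULL; truth <- NULL
  if (on("simulate")) {
    say("simulate: cohort of ", config$n_participants)
    truth <- sample_cohort(config$n_participants, config$task,
                           seed = config$seed, settings = config$cohort)
    trials <- simulate_trials(truth, seed = config$seed)
    participants <- truth$participants
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
    write_participants(participants,
                       file.path(config$out_dir, "participants.csv"))
    write_cohort_truth(truth, file.path(config$out_dir, "truth.json"))
    res$simulate <- list(n_participants = nrow(truth$participants),
                         n_trials = nrow(trials),
                         n_estimation = sum(trials$trial_type == "estimation"))
  } else if (!is.null(config$trials_csv)) {
    trials <- read_trials(config$trials_csv)
    if (!is.null(config$participants_csv)) {
      participants <- read_participants(config$participants_csv)
    }
    if (!is.null(config$truth_json)) {
      truth <- read_cohort_truth(config$truth_json)
    }
  }

  pre <- NULL
  if (on("preprocess")) {
    stopifnot(!is.null(trials))
    say("preprocess")
    pre <- preprocess_trials(trials)
    write_trials(pre$trials, file.path(config$out_dir, "trials_clean.csv"))
    res$preprocess <- list(
      n_excluded = sum(pre$excluded$excluded),
      excluded_ids = pre$excluded$participant_id[pre$excluded$excluded],
      n_trials_in = nrow(trials),
      n_trials_out = nrow(pre$trials),
      n_removed_by_mad = sum(pre$removed$n_removed))
    jsonlite::write_json(res$preprocess,
                         file.path(config$out_dir, "preprocessing.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  clean <- if (!is.null(pre)) pre$trials else trials
  perf <- if (!is.null(clean)) summarize_performance(clean) else NULL

  if (on("stats")) {
    stopifnot(!is.null(perf))
    say("stats: performance ANOVAs")
    acc <- rm_anova_2x2(perf$cells, value = "median_force_error")
    var_ <- rm_anova_2x2(perf$cells, value = "iqr_force_error")
    res$stats <- list(accuracy = as.list_table(acc),
                      variability = as.list_table(var_))
    readr::write_csv(dplyr::bind_rows(accuracy = acc, variability = var_,
                                      .id = "outcome"),
                     file.path(config$out_dir, "anova.csv"))
  }

  if (on("lmm")) {
    stopifnot(!is.null(clean))
    say("lmm: weighting-model selection")
    sel <- suppressWarnings(select_weighting_model(clean))
    res$lmm <- list(best = sel$best$spec_id,
                    slope = sel$best$fixed$estimate[2],
                    table = as.list_table(sel$table))
    readr::write_csv(sel$table, file.path(config$out_dir, "lmm_selection.csv"))
  }

  fits <- list()
  if (on("fit")) {
    stopifnot(!is.null(clean))
    for (v in config$variants) {
      say("fit: observer model ", v)
      fits[[v]] <- do.call(fit_observer, c(
        list(trials = clean, variant = v, seed = config$seed + 101L),
        config$sampler))
      readr::write_csv(fits[[v]]$cells,
                       file.path(config$out_dir,
                                 paste0("posterior_cells_", v, ".csv")))
      readr::write_csv(fits[[v]]$participants,
                       file.path(config$out_dir,
                                 paste0("posterior_participants_", v, ".csv")))
    }
    res$fit <- lapply(fits, function(f)
      list(variant = f$variant, max_rhat = max(f$rhat$rhat),
           mean_weight_w = mean(f$cells$weight_w)))
  }

  if (on("compare") && length(fits) >= 2) {
    say("compare: WAIC")
    cmp <- compare_waic(fits)
    res$compare <- list(best = cmp$best, table = as.list_table(cmp$table),
                        pairs = as.list_table(cmp$pairs))
    readr::write_csv(cmp$pairs, file.path(config$out_dir, "waic_pairs.csv"))
  }

  if (on("ppc") && length(fits) >= 1) {
    say("ppc")
    main <- fits[[intersect(c("m2", "m1", "m3"), names(fits))[1]]]
    ppc <- posterior_predictive(main, n_rep = config$n_ppc_rep,
                                seed = config$seed + 202L)
    res$ppc <- list(variant = main$variant,
                    coverage = as.list_table(ppc$coverage))
    readr::write_csv(ppc$coverage, file.path(config$out_dir, "ppc_coverage.csv"))
  }

  if (on("associate") && length(fits) >= 1 && !is.null(participants)) {
    say("associate: traits")
    main <- fits[[intersect(c("m2", "m1", "m3"), names(fits))[1]]]
    assoc <- associate_traits(extract_prior_sd(main), participants,
                              perf$participants)
    res$associate <- as.list_table(assoc)
    readr::write_csv(assoc, file.path(config$out_dir, "association.csv"))
  }

  if (on("recover") && length(fits) >= 1 && !is.null(truth)) {
    say("recover")
    main <- fits[[intersect(c("m2", "m1", "m3"), names(fits))[1]]]
    rec <- parameter_recovery(truth, main)
    res$recover <- as.list_table(rec)
    res$recovery_pass <- all(rec$pass)
    readr::write_csv(rec, file.path(config$out_dir, "recovery.csv"))
  }

  report <- generate_report(res, config)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", config$out_dir)
  invisible(report)
}

as.list_table <- function(df) lapply(seq_len(nrow(df)),
                                     function(i) as.list(df[i, ]))

#' Collate stage outputs into a machine-readable report
#'
#' @param results Named list of stage outputs (as built by
#'   [run_pipeline()]).
#' @param config The run configuration.
#' @return A list with `provenance` (seed, config hash, package version,
#'   timestamp) and `stages`.
#' @export
generate_report <- function(results, config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # hash must not depend on where outputs land
  list(
    provenance = list(
      package = "actionprior",
      version = as.character(utils::packageVersion("actionprior")),
      seed = config$seed,
      config_hash = rlang::hash(cfg),
      stages_run = config$stages,
      timestamp = format(Sys.time(), tz = "UTC")),
    stages = results)
}
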