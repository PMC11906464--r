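#' Pipeline configuration
#'
#' Settings for the end-to-end synthetic-study pipeline: the simulation
#' config plus MCMC, bootstrap and GLMM settings. Every stochastic stage is
#' seeded from `sim$seed` plus a fixed per-stage offset, so the whole report
#' is reproducible from one integer.
#'
#' @param sim A [sim_config()].
#' @param chains,iter,warmup MCMC settings forwarded to
#'   [fit_svo_by_condition()].
#' @param n_boot Mediation bootstrap samples.
#' @param participant_coding Mediation covariate coding, see
#'   [fit_mediation()].
#' @param glmm_structure Starting random-effects structure, see
#'   [fit_gaze_glmm()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), chains = 3, iter = 2000,
                            warmup = 500, n_boot = 5000,
                            participant_coding = "factor",
                            glmm_structure = "intercepts") {
  structure(list(sim = sim, chains = chains, iter = iter, warmup = warmup,
                 n_boot = n_boot, participant_coding = participant_coding,
                 glmm_structure = glmm_structure),
            class = "pipeline_config")
}

#' Per-participant, per-condition summaries
#'
#' Averages the trial-level data into the one-row-per-participant-per-
#' condition table the paired comparisons consume: mean log response time
#' and mean TFC, PTIS and Payne Index over valid trials (undefined PI trials
#' are dropped from the PI mean), plus posterior-mean `alpha` and `theta`
#' when a per-condition fit is supplied.
#'
#' @param trials Trial tibble (with `rt_ms`).
#' @param metrics Per-trial gaze metrics from [trial_gaze_metrics()].
#' @param fits Optional `svo_fit_by_condition`.
#' @return Tibble with `participant_id`, `condition` and measure columns.
#' @export
participant_condition_summaries <- function(trials, metrics, fits = NULL) {
  d <- left_join(trials, metrics[, c("participant_id", "trial_index", "tfc",
                                     "ptis", "payne_index", "valid")],
                 by = c("participant_id", "trial_index"))
  out <- d |>
    filter(.data$valid) |>
    group_by(.data$participant_id, .data$condition) |>
    summarise(
      log_rt = mean(log_transform_rt(.data$rt_ms)),
      tfc = mean(.data$tfc),
      ptis = mean(.data$ptis),
      payne_index = mean(.data$payne_index, na.rm = TRUE),
      .groups = "drop"
    )
  if (!is.null(fits)) {
    long <- tidyr::pivot_longer(
      fits$pairs,
      cols = -"participant_id",
      names_to = c("measure", "condition"), names_sep = "_",
      values_to = "value"
    ) |>
      mutate(condition = ifelse(.data$condition == "svor", "SVOR", "IC")) |>
      tidyr::pivot_wider(names_from = "measure", values_from = "value")
    out <- left_join(out, long, by = c("participant_id", "condition"))
  }
  out
}

#' Run the full synthetic-study pipeline
#'
#' Composes every stage on simulated data: stimulus generation, study
#' simulation, gaze-metric computation, per-condition hierarchical fits,
#' paired condition comparisons (alpha, theta, log RT, TFC, PTIS, PI) with
#' JZS Bayes factors, the parallel multiple-mediator model, and the
#' time-advantage GLMM. Deterministic given the config's seed. If `out_dir`
#' is given, flat CSV/JSON artefacts are written there for downstream use.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return An object of class `svo_study_report`: a list with `$study`,
#'   `$metrics`, `$fits`, `$comparisons`, `$mediation`, `$glmm`,
#'   `$validation` and a `$provenance` block (seeds and settings).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- simulate_study(config$sim)
  metrics <- trial_gaze_metrics(study$fixations, study$trials, study$battery)
  validation <- validate_dataset(study$trials, study$fixations, study$battery)
  trials_joined <- left_join(study$trials,
                             study$battery[, c("pair_id", "own_a", "other_a",
                                               "own_b", "other_b")],
                             by = "pair_id")
  fits <- fit_svo_by_condition(trials_joined, chains = config$chains,
                               iter = config$iter, warmup = config$warmup,
                               seed = config$sim$seed + 100L)
  summaries <- participant_condition_summaries(study$trials, metrics, fits)
  comparisons <- list_rbind(lapply(
    c("alpha", "theta", "log_rt", "tfc", "ptis", "payne_index"),
    function(m) condition_comparison(summaries, m)
  ))
  merged <- left_join(study$trials, metrics[, c("participant_id",
                                                "trial_index", "pair_id",
                                                "tfc", "ptis", "payne_index",
                                                "time_advantage", "valid")],
                      by = c("participant_id", "trial_index", "pair_id"))
  analysed <- merged[merged$valid, , drop = FALSE]
  mediation <- fit_mediation(analysed, n_boot = config$n_boot,
                             seed = config$sim$seed + 200L,
                             participant_coding = config$participant_coding)
  glmm <- fit_gaze_glmm(analysed, random_structure = config$glmm_structure)
  report <- structure(
    list(study = study, metrics = metrics, fits = fits,
         summaries = summaries, comparisons = comparisons,
         mediation = mediation, glmm = glmm, validation = validation,
         provenance = list(
           seed = config$sim$seed,
           package_version = as.character(utils::packageVersion("svogaze")),
           mcmc = list(chains = config$chains, iter = config$iter,
                       warmup = config$warmup),
           n_boot = config$n_boot,
           n_trials = nrow(study$trials),
           n_excluded_gaze = sum(!metrics$valid)
         )),
    class = "svo_study_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.svo_study_report <- function(x, ...) {
  p <- x$provenance
  cat("Synthetic allocation-study report\n")
  cat(sprintf("  %d trials (%d excluded for missing gaze), seed %d\n",
              p$n_trials, p$n_excluded_gaze, p$seed))
  cat("Condition comparisons (SVOR vs IC):\n")
  print(x$comparisons[, c("measure", "m_svor", "m_ic", "t", "p", "d",
                          "bf10", "evidence")])
  cat("Mediation (indirect effects):\n")
  print(x$mediation$paths[, c("mediator", "indirect", "ci_lower", "ci_upper",
                              "p")])
  cat("Time-advantage simple slopes:\n")
  print(x$glmm$slopes[, c("condition", "slope", "odds_ratio", "p")])
  invisible(x)
}

#' Write pipeline artefacts as flat files
#'
#' CSV for the tabular stages (stimuli, trials, fixations, metrics,
#' summaries, comparisons) and JSON for the fitted-model summaries and the
#' provenance block.
#'
#' @param report An `svo_study_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$study$battery, file.path(dir, "stimuli.csv"))
  readr::write_csv(report$study$trials, file.path(dir, "trials.csv"))
  readr::write_csv(report$study$fixations, file.path(dir, "fixations.csv"))
  readr::write_csv(report$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(report$summaries, file.path(dir, "summaries.csv"))
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"))
  jsonlite::write_json(
    list(
      fit = list(SVOR = glance(report$fits$fits$SVOR),
                 IC = glance(report$fits$fits$IC)),
      mediation = list(paths = report$mediation$paths,
                       effects = report$mediation$effects),
      glmm = list(fixed = report$glmm$fixed, slopes = report$glmm$slopes,
                  random_structure = report$glmm$random_structure),
      provenance = report$provenance
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Validate a dataset's referential and structural integrity
#'
#' Checks that every trial's `pair_id` exists in the stimulus battery, every
#' fixation row maps to a known trial, response times are positive, trial
#' indices are unique within participant, IC pairs satisfy the equal-gap
#' invariant, and counts how many trials lack fixation data (the exclusion
#' accounting). Violations are reported, not thrown.
#'
#' @param trials,fixations,stimuli The three data tables.
#' @return A list of class `svo_validation`: `$violations` (tibble of
#'   `check`, `n`, `detail`) and `$counts` (trials, fixations, trials
#'   without gaze data).
#' @export
validate_dataset <- function(trials, fixations, stimuli) {
  v <- list()
  bad_pair <- !trials$pair_id %in% stimuli$pair_id
  if (any(bad_pair)) {
    v[[length(v) + 1]] <- tibble(check = "unknown pair_id", n = sum(bad_pair),
                                 detail = paste(unique(trials$pair_id[bad_pair]),
                                                collapse = ", "))
  }
  trial_key <- paste(trials$participant_id, trials$trial_index)
  fix_key <- paste(fixations$participant_id, fixations$trial_index)
  orphan <- !fix_key %in% trial_key
  if (any(orphan)) {
    v[[length(v) + 1]] <- tibble(check = "fixation without trial",
                                 n = sum(orphan),
                                 detail = paste(head(unique(fix_key[orphan]), 5),
                                                collapse = "; "))
  }
  bad_rt <- !is.na(trials$rt_ms) & trials$rt_ms <= 0
  if (any(bad_rt)) {
    v[[length(v) + 1]] <- tibble(check = "non-positive rt_ms", n = sum(bad_rt),
                                 detail = "")
  }
  dup <- duplicated(trial_key)
  if (any(dup)) {
    v[[length(v) + 1]] <- tibble(check = "duplicate trial_index within participant",
                                 n = sum(dup), detail = "")
  }
  ic_bad <- tryCatch({
    validate_stimuli(stimuli)
    0L
  }, error = function(e) NA_integer_)
  if (is.na(ic_bad)) {
    v[[length(v) + 1]] <- tibble(check = "stimulus battery invalid", n = 1L,
                                 detail = "see validate_stimuli()")
  }
  no_gaze <- sum(!trial_key %in% fix_key)
  violations <- if (length(v) == 0) {
    tibble(check = character(0), n = integer(0), detail = character(0))
  } else {
    bind_rows(v)
  }
  structure(
    list(violations = violations,
         counts = list(n_trials = nrow(trials), n_fixations = nrow(fixations),
                       n_trials_without_gaze = no_gaze)),
    class = "svo_validation"
  )
}

#' @export
print.svo_validation <- function(x, ...) {
  cat(sprintf("Dataset validation: %d trials, %d fixations, %d trial(s) without gaze data\n",
              x$counts$n_trials, x$counts$n_fixations,
              x$counts$n_trials_without_gaze))
  if (nrow(x$violations) == 0) {
    cat("  no violations\n")
  } else {
    cat(sprintf("  %d violation type(s):\n", nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

#' Read trial and fixation logs from CSV
#'
#' Plain-CSV loaders for the trial-log and fixation-report formats written
#' by [write_report()] (and by eye-tracker fixation-report exports massaged
#' into the same columns).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    trial_index = readr::col_integer(),
    pair_id = readr::col_character(),
    condition = readr::col_character(),
    choice = readr::col_character(),
    chose_selfish = readr::col_integer(),
    rt_ms = readr::col_double()
  ))
}

#' @rdname read_trials
#' @export
read_fixations <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    trial_index = readr::col_integer(),
    fixation_index = readr::col_integer(),
    roi = readr::col_character(),
    onset_ms = readr::col_double(),
    duration_ms = readr::col_double()
  ))
}
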