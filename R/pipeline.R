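## End-to-end orchestration: simulate -> label -> featurize -> evaluate ->
## explain, driven by one config and one seed.

#' Label a cohort end to end
#'
#' Trims the initial observation-effect window, labels days and weeks.
#'
#' @param events `adhera_event_log`.
#' @param config `adhera_config`.
#' @return list with `daily` and `weekly` records.
#' @export
label_cohort <- function(events, config = default_config()) {
  trimmed <- trim_hawthorne(events, config$hawthorne_trim_days)
  daily <- label_daily(trimmed, config$window_hours)
  weekly <- label_weekly(daily, config$weekly_threshold,
                         circular = config$circular_time)
  list(daily = daily, weekly = weekly)
}

#' Build model-ready samples for one task
#'
#' Builds the lagged tensor, filters static features by availability and
#' joins them to samples by carry-forward of the most recent completed
#' survey timepoint.
#'
#' @param labels list from [label_cohort()].
#' @param static data.frame of per-subject, per-timepoint scale scores
#'   (e.g. the synthetic survey, or the output of [score_scales()]).
#' @param task "daily" or "weekly".
#' @param config `adhera_config`.
#' @param start_dates named Date vector anchoring each subject's
#'   timepoints; defaults to each subject's first labeled date.
#' @return `adhera_samples` with static block attached.
#' @export
build_task_samples <- function(labels, static, task = c("daily", "weekly"),
                               config = default_config(),
                               start_dates = NULL) {
  task <- match.arg(task)
  samples <- if (task == "daily") {
    build_daily_samples(labels$daily, config$daily_lag)
  } else {
    build_weekly_samples(labels$weekly, config$weekly_lag)
  }
  if (is.null(static)) return(samples)
  if (is.null(start_dates)) {
    start_dates <- vapply(split(labels$daily$date, labels$daily$subject_id),
                          min, numeric(1L))
    start_dates <- stats::setNames(as.Date(start_dates,
                                           origin = "1970-01-01"),
                                   names(start_dates))
  }
  static_f <- filter_availability(static, config$availability_threshold)
  align_static(static_f, samples, start_dates)
}

#' Fit a fusion model on a full sample set
#'
#' Convenience fit outside cross-validation (used for attribution
#' reports): preprocessing is fitted on the given samples, SMOTE balances
#' the classes, and the fusion model is trained on all features.
#'
#' @param samples `adhera_samples`.
#' @param config `adhera_config`.
#' @param seed training seed (default: config seed).
#' @return list with the trained `model` and the preprocessed `samples`
#'   (for explaining).
#' @export
fit_fusion <- function(samples, config = default_config(),
                       seed = config$seed) {
  pp <- preprocess_fold(samples)
  tr <- pp$train
  sm <- smote_fold(tr, derive_seed(seed, "fit_smote"))
  args <- config$fusion[intersect(names(config$fusion),
                                  names(formals(fusion_config)))]
  args$seed <- derive_seed(seed, "fit_fusion")
  fcfg <- do.call(fusion_config, args)
  model <- build_fusion(fcfg, dim(tr$dynamic)[2L], dim(tr$dynamic)[3L],
                        if (is.null(tr$static)) 0L else ncol(tr$static),
                        channels = tr$channels,
                        static_names = colnames(tr$static))
  model <- train_model(model, sm$samples)
  list(model = model, samples = tr)
}

#' Run the full pipeline from a config
#'
#' Executes simulate (or load) -> label -> featurize -> nested CV ->
#' attribution, writing every artifact plus a run manifest under
#' `out_dir`. A rerun with the same config and seed reproduces the metric
#' tables.
#'
#' @param config an `adhera_config`, or a path to a YAML config (see
#'   [read_config()]); the config may carry a `synthetic` block
#'   (simulation parameters), a `task` ("daily", "weekly" or "both") and a
#'   `models` vector.
#' @param out_dir output directory.
#' @param events,survey optional paths to existing event-log / survey CSVs
#'   (used when no `synthetic` block is present).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, events = NULL, survey = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- read_config(config)
  }
  config <- validate_config(config)
  task <- config$task %||% "both"
  if (!task %in% c("daily", "weekly", "both")) {
    stop("config 'task' must be daily, weekly or both", call. = FALSE)
  }
  models <- canonical_model_kind(config$models %||%
                                   c("fusion", "logistic_regression"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(config$synthetic)) {
    cohort <- stage("simulate", {
      sp <- config$synthetic
      sp$seed <- sp$seed %||% derive_seed(config$seed, "simulate")
      generate_cohort(do.call(cohort_params, sp))
    })
    ev <- cohort$events
    sv <- cohort$survey
    write_event_log(ev, file.path(out_dir, "events.csv"))
    utils::write.csv(sv, file.path(out_dir, "survey.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(
      list(archetype = cohort$truth$archetype,
           p_adh = cohort$truth$p_adh,
           params = cohort$truth$params[setdiff(names(cohort$truth$params),
                                                "beta")],
           beta = as.list(cohort$truth$params$beta)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    if (is.null(events)) stop("no synthetic block and no events path",
                              call. = FALSE)
    ev <- stage("load", read_event_log(events))
    sv <- if (!is.null(survey)) stage("load", read_survey_table(survey))
  }
  start_dates <- vapply(split(ev$timestamp, ev$subject_id),
                        function(ts) as.numeric(as.Date(min(ts), tz = "UTC")),
                        numeric(1L))
  start_dates <- stats::setNames(as.Date(start_dates, origin = "1970-01-01"),
                                 names(start_dates))
  labels <- stage("label", label_cohort(ev, config))
  utils::write.csv(labels$daily, file.path(out_dir, "daily.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(labels$weekly, file.path(out_dir, "weekly.csv"),
                   row.names = FALSE, na = "")
  tasks <- if (task == "both") c("daily", "weekly") else task
  outputs <- list()
  for (tk in tasks) {
    samples <- stage("featurize",
                     build_task_samples(labels, sv, tk, config, start_dates))
    report <- stage("evaluate", run_nested_cv(samples, models, config))
    paths <- write_reports(report, file.path(out_dir,
                                             paste0("cv_", tk)))
    imp_path <- NULL
    if ("fusion" %in% models) {
      imp <- stage("explain", explain_cv(samples, config))
      imp_path <- write_reports(imp, file.path(out_dir,
                                               paste0("importance_", tk)))
    }
    outputs[[tk]] <- list(cv = unname(paths),
                          importance = unname(imp_path))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("adhera")),
    seed = config$seed,
    config_hash = if (!is.null(cfg_path))
      unname(tools::md5sum(cfg_path)) else NA_character_,
    input_digests = if (is.null(config$synthetic))
      as.list(tools::md5sum(c(events, survey))) else "synthetic",
    tasks = tasks, models = models, outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
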