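#' Default run configuration
#'
#' Assembles the configuration that drives labeling, feature building and
#' model evaluation. Defaults follow the once-daily adjuvant endocrine
#' therapy setting: a dose is on time when it falls 24 +/- 6 hours after the
#' previous one, a week counts as adherent above 80 percent of days, the
#' first month of device data is discarded (observation effect), survey
#' features need 60 percent availability and scales need Cronbach's alpha
#' of at least 0.7.
#'
#' @param daily_lag number of lagged days feeding the daily model.
#' @param weekly_lag number of lagged weeks feeding the weekly model.
#' @param window_hours closed interval, in hours since the previous opening,
#'   inside which a dose counts as adherent.
#' @param weekly_threshold strict lower bound on the adherent-day fraction
#'   for a week to count as adherent.
#' @param hawthorne_trim_days days removed from the start of each subject's
#'   event stream before labeling.
#' @param availability_threshold minimum non-missing fraction for a static
#'   feature to be kept (computed on training subjects).
#' @param alpha_cutoff minimum Cronbach's alpha for a scale to be kept.
#' @param cv_folds number of outer (and inner) cross-validation folds.
#' @param seed master seed; all stage seeds derive from it.
#' @param circular_time use circular mean/sd for weekly dosing-hour
#'   statistics instead of naive arithmetic ones.
#' @param fusion named list of fusion-model hyperparameters (see
#'   [fusion_config()]); entries with multiple values form the tuning grid.
#' @param baselines named list of per-baseline hyperparameter grids.
#' @return a validated list of class `adhera_config`.
#' @export
default_config <- function(daily_lag = 7L,
                           weekly_lag = 4L,
                           window_hours = c(18, 30),
                           weekly_threshold = 0.80,
                           hawthorne_trim_days = 30L,
                           availability_threshold = 0.60,
                           alpha_cutoff = 0.70,
                           cv_folds = 5L,
                           seed = 1L,
                           circular_time = FALSE,
                           fusion = list(),
                           baselines = list()) {
  cfg <- list(
    daily_lag = as.integer(daily_lag),
    weekly_lag = as.integer(weekly_lag),
    window_hours = as.numeric(window_hours),
    weekly_threshold = weekly_threshold,
    hawthorne_trim_days = as.integer(hawthorne_trim_days),
    availability_threshold = availability_threshold,
    alpha_cutoff = alpha_cutoff,
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed),
    circular_time = isTRUE(circular_time),
    fusion = utils::modifyList(default_fusion_grid(), fusion),
    baselines = utils::modifyList(default_baseline_grids(), baselines)
  )
  validate_config(cfg)
}

default_fusion_grid <- function() {
  list(lstm_units = 16L, static_units = 8L, fusion_units = 8L,
       dropout = 0.2, learning_rate = 0.01, batch_size = 64L,
       max_epochs = 40L, patience = 5L, validation_fraction = 0.15)
}

default_baseline_grids <- function() {
  list(
    random_forest = list(ntree = 300L, mtry = NULL),
    svm = list(cost = 1, gamma = NULL),
    gradient_boosted_trees = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
    logistic_regression = list()
  )
}

#' Validate a run configuration
#'
#' @param cfg list as produced by [default_config()] or read from YAML.
#' @return the config, invisibly classed `adhera_config`; stops on invalid
#'   values.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$window_hours) != 2L ||
      !(cfg$window_hours[1] < 24 && 24 < cfg$window_hours[2])) {
    stop("window_hours must bracket 24 h (lower < 24 < upper)", call. = FALSE)
  }
  for (nm in c("weekly_threshold", "availability_threshold")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop(nm, " must lie strictly between 0 and 1", call. = FALSE)
    }
  }
  if (cfg$cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  if (cfg$hawthorne_trim_days < 0L) stop("hawthorne_trim_days must be >= 0",
                                         call. = FALSE)
  if (cfg$daily_lag < 1L || cfg$weekly_lag < 1L) {
    stop("lags must be >= 1", call. = FALSE)
  }
  class(cfg) <- c("adhera_config", "list")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so that typos fail loudly before any compute.
#'
#' @param path YAML file.
#' @return validated `adhera_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(default_config))
  extra <- setdiff(names(raw), c(known, "synthetic", "task", "models"))
  if (length(extra) > 0L) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cfg <- do.call(default_config, raw[intersect(names(raw), known)])
  cfg$synthetic <- raw$synthetic
  cfg$task <- raw$task
  cfg$models <- raw$models
  cfg
}
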