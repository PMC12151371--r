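## I/O: event logs, survey tables, reports.

TIMEPOINTS <- c("baseline", "month4", "month8")

parse_timestamps <- function(x) {
  # ISO-8601 to minute precision, timezone-naive local clock time.
  # DST discontinuities are deliberately ignored: the behavioral signal is
  # the clock hour at which the bottle was opened.
  x <- trimws(as.character(x))
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
            "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  todo <- rep(TRUE, length(x))
  for (f in fmts) {
    if (!any(todo)) break
    p <- as.POSIXct(x[todo], format = f, tz = "UTC")
    ok <- !is.na(p)
    out[todo][ok] <- p[ok]
    todo[todo] <- !ok
  }
  trunc(out, units = "mins")
}

#' Read a medication-event log
#'
#' Reads one timestamped bottle-opening record per row, sorts events within
#' subject, and collapses duplicate openings within the same minute (device
#' chatter, not dosing).
#'
#' @param path CSV file with a header row.
#' @param col_map named list mapping the roles `subject` and `timestamp` to
#'   column names in the file.
#' @return a data.frame of class `adhera_event_log` with columns
#'   `subject_id` (character) and `timestamp` (POSIXct, minute precision),
#'   sorted by subject then time.
#' @export
read_event_log <- function(path, col_map = list(subject = "subject_id",
                                                timestamp = "timestamp")) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("event log is empty: ", path, call. = FALSE)
  for (role in c("subject", "timestamp")) {
    if (!col_map[[role]] %in% names(df)) {
      stop("column '", col_map[[role]], "' (", role, ") not found in ", path,
           call. = FALSE)
    }
  }
  ts <- parse_timestamps(df[[col_map$timestamp]])
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop("unparseable timestamp at row ", bad, ": '",
         df[[col_map$timestamp]][bad], "'", call. = FALSE)
  }
  out <- data.frame(subject_id = as.character(df[[col_map$subject]]),
                    timestamp = ts, stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$timestamp), , drop = FALSE]
  dup <- duplicated(out[c("subject_id", "timestamp")])
  if (any(dup)) {
    adhera_log("collapsed ", sum(dup), " duplicate same-minute opening(s)")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("adhera_event_log", "data.frame")
  out
}

#' Construct an event log from a data.frame
#'
#' Applies the same invariants as [read_event_log()] (sorted per subject,
#' same-minute duplicates collapsed) without touching disk.
#'
#' @param df data.frame with columns `subject_id` and `timestamp`
#'   (POSIXct or ISO-8601 strings).
#' @return `adhera_event_log`.
#' @export
as_event_log <- function(df) {
  stopifnot(all(c("subject_id", "timestamp") %in% names(df)))
  ts <- if (inherits(df$timestamp, "POSIXct")) {
    trunc(df$timestamp, units = "mins")
  } else parse_timestamps(df$timestamp)
  if (anyNA(ts)) stop("unparseable timestamp in data", call. = FALSE)
  out <- data.frame(subject_id = as.character(df$subject_id),
                    timestamp = as.POSIXct(ts, tz = "UTC"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$timestamp), , drop = FALSE]
  out <- out[!duplicated(out[c("subject_id", "timestamp")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("adhera_event_log", "data.frame")
  out
}

#' Write an event log to CSV
#' @param log `adhera_event_log`.
#' @param path output CSV path.
#' @export
write_event_log <- function(log, path) {
  df <- data.frame(subject_id = log$subject_id,
                   timestamp = format(log$timestamp, "%Y-%m-%dT%H:%M"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survey table
#'
#' One row per (subject, timepoint); blank cells become `NA` and are never
#' dropped. Timepoints must be one of `baseline`, `month4`, `month8`.
#'
#' @param path CSV with columns `subject_id`, `timepoint`, then one column
#'   per survey variable.
#' @return data.frame of class `adhera_survey`.
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop("survey table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!all(c("subject_id", "timepoint") %in% names(df))) {
    stop("survey table needs columns subject_id and timepoint", call. = FALSE)
  }
  bad <- setdiff(unique(df$timepoint), TIMEPOINTS)
  if (length(bad) > 0L) {
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(TIMEPOINTS, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[c("subject_id", "timepoint")])) {
    stop("duplicate (subject, timepoint) rows in survey table", call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  class(df) <- c("adhera_survey", "data.frame")
  df
}

#' Write cross-validation or importance reports
#'
#' Emits a machine-readable JSON report plus a flat CSV metric table;
#' reading the JSON back reproduces all values exactly (no rounding).
#'
#' @param report an `adhera_cv_report` or `adhera_importance` object.
#' @param path output path *stem*; `<stem>.json` and `<stem>.csv` are
#'   written.
#' @return paths written, invisibly.
#' @export
write_reports <- function(report, path) {
  if (is.null(report) || length(report) == 0L) {
    stop("refusing to write an empty report", call. = FALSE)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, ".csv")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  tab <- if (inherits(report, "adhera_cv_report")) cv_metric_table(report)
         else if (inherits(report, "adhera_importance")) report$table
         else as.data.frame(report)
  utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Read a previously written JSON report
#' @param path path to the `.json` file written by [write_reports()].
#' @return the report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
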