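## Daily and weekly adherence labeling from bottle-opening event streams.

EPOCH_LEVELS <- c("Morning", "Afternoon", "Evening", "Night")

#' Assign a time-of-day epoch
#'
#' Partitions the 24-hour clock into four half-open bins:
#' Morning \[06:00, 12:00), Afternoon \[12:00, 18:00),
#' Evening \[18:00, 24:00), Night \[00:00, 06:00).
#'
#' @param hour numeric decimal hour(s) in \[0, 24).
#' @return character vector of epochs.
#' @export
assign_epoch <- function(hour) {
  stopifnot(all(hour >= 0 & hour < 24, na.rm = TRUE))
  out <- rep(NA_character_, length(hour))
  out[hour >= 6 & hour < 12] <- "Morning"
  out[hour >= 12 & hour < 18] <- "Afternoon"
  out[hour >= 18] <- "Evening"
  out[hour < 6] <- "Night"
  out
}

#' Trim the initial observation-effect window
#'
#' Removes, per subject, all events within `trim_days` days of that
#' subject's first event. Monitoring awareness typically inflates adherence
#' at the start of data collection, so the first month is discarded before
#' labeling. Subjects left with no events are dropped.
#'
#' @param log `adhera_event_log`.
#' @param trim_days nonnegative number of days to discard.
#' @return trimmed `adhera_event_log`.
#' @export
trim_hawthorne <- function(log, trim_days = 30) {
  stopifnot(trim_days >= 0)
  if (trim_days == 0 || nrow(log) == 0L) return(log)
  keep <- unlist(lapply(split(seq_len(nrow(log)), log$subject_id), function(ix) {
    t0 <- min(log$timestamp[ix])
    ix[as.numeric(difftime(log$timestamp[ix], t0, units = "days")) >= trim_days]
  }), use.names = FALSE)
  dropped <- setdiff(unique(log$subject_id), unique(log$subject_id[keep]))
  if (length(dropped) > 0L) {
    adhera_log("trim_hawthorne dropped subject(s) with no remaining events: ",
               paste(dropped, collapse = ", "))
  }
  out <- log[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

decimal_hour <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

is_weekend_date <- function(date) {
  # POSIXlt wday: 0 = Sunday, 6 = Saturday
  as.POSIXlt(date)$wday %in% c(0L, 6L)
}

#' Label daily adherence
#'
#' Converts an event stream into one record per calendar day, from the day
#' after each subject's first event-day through the subject's last
#' event-day. A day with an opening is adherent iff the interval since the
#' previous opening lies in the closed window (default \[18, 30\] hours,
#' i.e. 24 +/- 6 h); a day with no opening is non-adherent. When a day has
#' several openings, the first one defines the day's event time, epoch and
#' inter-dose interval.
#'
#' @param log `adhera_event_log` (sorted per subject; use
#'   [trim_hawthorne()] first if desired).
#' @param window closed adherence window in hours since the previous
#'   opening.
#' @return data.frame of class `adhera_daily` with columns `subject_id`,
#'   `date`, `has_event`, `event_hour`, `inter_dose_hours`, `is_adherent`,
#'   `epoch`, `is_weekend`.
#' @export
label_daily <- function(log, window = c(18, 30)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  empty <- data.frame(subject_id = character(), date = as.Date(character()),
                      has_event = integer(), event_hour = numeric(),
                      inter_dose_hours = numeric(), is_adherent = integer(),
                      epoch = character(), is_weekend = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(log) == 0L) {
    class(empty) <- c("adhera_daily", "data.frame")
    return(empty)
  }
  parts <- lapply(split(log$timestamp, log$subject_id), function(ts) {
    ts <- sort(ts)
    days <- as.Date(ts, tz = "UTC")
    first_day <- days[1L]
    last_day <- days[length(days)]
    if (last_day <= first_day) return(NULL)  # needs >= 2 distinct days
    cal <- seq(first_day + 1L, last_day, by = "day")
    # first opening of each day, and the opening immediately preceding it
    first_of_day <- !duplicated(days)
    ft <- ts[first_of_day]
    fd <- days[first_of_day]
    # previous opening overall = event just before the day's first event
    idx <- match(ft, ts)
    prev <- rep(as.POSIXct(NA, tz = "UTC"), length(idx))
    prev[idx > 1L] <- ts[idx[idx > 1L] - 1L]
    m <- match(cal, fd)
    has_event <- as.integer(!is.na(m))
    event_hour <- ifelse(is.na(m), NA_real_, decimal_hour(ft[m]))
    inter <- ifelse(is.na(m), NA_real_,
                    as.numeric(difftime(ft[m], prev[m], units = "hours")))
    data.frame(date = cal, has_event = has_event, event_hour = event_hour,
               inter_dose_hours = inter, stringsAsFactors = FALSE)
  })
  keep <- !vapply(parts, is.null, logical(1L))
  if (!any(keep)) {
    class(empty) <- c("adhera_daily", "data.frame")
    return(empty)
  }
  parts <- parts[keep]
  out <- do.call(rbind, Map(function(sid, df) {
    df$subject_id <- sid
    df
  }, names(parts), parts))
  out$is_adherent <- as.integer(out$has_event == 1L &
                                  !is.na(out$inter_dose_hours) &
                                  out$inter_dose_hours >= window[1] &
                                  out$inter_dose_hours <= window[2])
  out$epoch <- ifelse(out$has_event == 1L, assign_epoch(out$event_hour),
                      NA_character_)
  out$is_weekend <- as.integer(is_weekend_date(out$date))
  out <- out[c("subject_id", "date", "has_event", "event_hour",
               "inter_dose_hours", "is_adherent", "epoch", "is_weekend")]
  rownames(out) <- NULL
  class(out) <- c("adhera_daily", "data.frame")
  out
}

circ_hour_stats <- function(hours) {
  # circular mean/sd on the 24 h clock, reported in hours
  theta <- hours / 24 * 2 * pi
  C <- mean(cos(theta)); S <- mean(sin(theta))
  R <- sqrt(C^2 + S^2)
  mu <- atan2(S, C) %% (2 * pi)
  sdc <- if (R > 0) sqrt(-2 * log(R)) else pi
  c(mean = mu / (2 * pi) * 24, sd = sdc / (2 * pi) * 24)
}

#' Label weekly adherence
#'
#' Partitions each subject's contiguous daily records into consecutive
#' 7-day blocks anchored at the first labeled day (trailing partial week
#' dropped). A week is adherent when more than 80 percent of its days are
#' adherent, i.e. at least 6 of 7 under a once-daily regimen. Also derives
#' the weekend adherence level (0/50/100), the modal dosing epoch (ties
#' broken Morning > Afternoon > Evening > Night), and the mean and standard
#' deviation of the dosing hour over the week's event days.
#'
#' @param daily `adhera_daily` records, contiguous per subject.
#' @param threshold strict lower bound on the adherent-day fraction.
#' @param circular use circular statistics for the hour mean/sd.
#' @return data.frame of class `adhera_weekly` with columns `subject_id`,
#'   `week_index`, `n_adherent_days`, `is_adherent_wk`, `weekend_adh_level`,
#'   `modal_epoch`, `time_mean`, `time_std`.
#' @export
label_weekly <- function(daily, threshold = 0.80, circular = FALSE) {
  parts <- split(daily, daily$subject_id)
  rows <- lapply(names(parts), function(sid) {
    d <- parts[[sid]]
    d <- d[order(d$date), , drop = FALSE]
    n_weeks <- nrow(d) %/% 7L
    if (n_weeks == 0L) {
      adhera_log("subject ", sid, " has fewer than 7 labeled days; ",
                 "no weekly records")
      return(NULL)
    }
    do.call(rbind, lapply(seq_len(n_weeks), function(w) {
      blk <- d[((w - 1L) * 7L + 1L):(w * 7L), , drop = FALSE]
      n_adh <- sum(blk$is_adherent)
      wkend <- blk[blk$is_weekend == 1L, , drop = FALSE]
      lvl <- round(100 * sum(wkend$is_adherent) / 2 / 50) * 50
      ev <- blk[blk$has_event == 1L, , drop = FALSE]
      if (nrow(ev) == 0L) {
        tm <- NA_real_; tsd <- NA_real_; mep <- NA_character_
      } else {
        if (circular) {
          st <- circ_hour_stats(ev$event_hour)
          tm <- st[["mean"]]
          tsd <- if (nrow(ev) == 1L) 0 else st[["sd"]]
        } else {
          tm <- mean(ev$event_hour)
          tsd <- if (nrow(ev) == 1L) 0 else stats::sd(ev$event_hour)
        }
        mep <- modal_value(ev$epoch, EPOCH_LEVELS)
      }
      data.frame(subject_id = sid, week_index = w,
                 week_start = blk$date[1L], n_adherent_days = n_adh,
                 is_adherent_wk = as.integer(n_adh / 7 > threshold),
                 weekend_adh_level = lvl, modal_epoch = mep,
                 time_mean = tm, time_std = tsd, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), week_index = integer(),
                      week_start = as.Date(character()),
                      n_adherent_days = integer(), is_adherent_wk = integer(),
                      weekend_adh_level = numeric(), modal_epoch = character(),
                      time_mean = numeric(), time_std = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("adhera_weekly", "data.frame")
  out
}
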