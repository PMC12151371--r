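# Independent oracles and fixture builders used across the suite.
# The day-walk oracle below deliberately shares no code with label_daily():
# it walks calendar days one at a time with scalar arithmetic.

# Brute-force daily labeler: for one subject's sorted POSIXct events,
# walk every calendar day after the first event-day and decide adherence
# from the raw inter-opening gap of the day's first opening.
oracle_label_daily_one <- function(ts, lo = 18, hi = 30) {
  ts <- sort(ts)
  days <- as.Date(ts, tz = "UTC")
  if (length(ts) < 1L || days[length(days)] <= days[1L]) {
    return(NULL)
  }
  out <- list()
  day <- days[1L] + 1L
  while (day <= days[length(days)]) {
    todays <- ts[days == day]
    if (length(todays) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        date = day, has_event = 0L, is_adherent = 0L)
    } else {
      first <- min(todays)
      before <- ts[ts < first]
      gap <- as.numeric(difftime(first, max(before), units = "hours"))
      out[[length(out) + 1L]] <- data.frame(
        date = day, has_event = 1L,
        is_adherent = as.integer(gap >= lo & gap <= hi))
    }
    day <- day + 1L
  }
  do.call(rbind, out)
}

# Random event stream with gaps, double doses and boundary intervals.
random_event_stream <- function(n_days = 30, p_take = 0.8, p_double = 0.1) {
  t0 <- as.POSIXct("2021-03-01 08:00", tz = "UTC")
  ts <- c()
  cur <- t0
  for (d in seq_len(n_days)) {
    if (stats::runif(1) < p_take) {
      # gap drawn to straddle the 18/30 h boundaries often
      gap <- sample(c(12, 17.99, 18, 20, 24, 26, 30, 30.02, 36, 48), 1L) +
        stats::runif(1, -0.3, 0.3)
      cur <- cur + round(gap * 60) * 60
      ts <- c(ts, cur)
      if (stats::runif(1) < p_double) {
        ts <- c(ts, cur + round(stats::runif(1, 10, 300)) * 60)
      }
    } else {
      cur <- cur + 24 * 3600
    }
  }
  sort(unique(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC")))
}

make_event_log <- function(sid, stamps) {
  as_event_log(data.frame(subject_id = sid,
                          timestamp = as.POSIXct(stamps, tz = "UTC")))
}

# Small labeled cohort reused by feature/model tests.
tiny_cohort <- function(n_subjects = 12, n_days = 120, seed = 42, ...) {
  coh <- generate_cohort(cohort_params(n_subjects = n_subjects,
                                       n_days = n_days, seed = seed, ...))
  cfg <- default_config(seed = seed)
  labs <- label_cohort(coh$events, cfg)
  starts <- vapply(split(coh$events$timestamp, coh$events$subject_id),
                   function(ts) as.numeric(as.Date(min(ts), tz = "UTC")),
                   numeric(1L))
  starts <- stats::setNames(as.Date(starts, origin = "1970-01-01"),
                            names(starts))
  list(cohort = coh, config = cfg, labels = labs, starts = starts)
}
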