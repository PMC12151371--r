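## Synthetic cohort generator: event logs + survey tables with planted,
## recoverable behavioral structure.

#' Parameters for a synthetic adherence cohort
#'
#' The generator emulates a once-daily oral regimen monitored by a smart
#' pill bottle over roughly eight months, in a cohort the size of a typical
#' adherence RCT. Daily taken/missed states follow a two-state Markov
#' chain: with probability `rho` the subject repeats yesterday's state,
#' otherwise a fresh state is drawn from the subject's adherence
#' probability, which is shifted additively on the miss scale by `delta_w`
#' on weekends, multiplied by `hawthorne_boost` (on the miss scale) during
#' the initial monitoring-awareness window, and modulated on the log-odds
#' scale by static covariates. Subjects split into "regular" dosers with
#' small dosing-time jitter and "irregular" dosers with large jitter.
#'
#' @param n_subjects cohort size.
#' @param n_days days of monitoring per subject.
#' @param p_base baseline daily probability of taking the dose.
#' @param rho habit persistence: probability of repeating yesterday's state.
#' @param delta_w additive weekend shift to the daily miss probability.
#' @param hawthorne_days length of the initial high-adherence window.
#' @param hawthorne_boost multiplier (< 1) on the miss probability during
#'   that window.
#' @param frac_irregular fraction of subjects with irregular dosing times.
#' @param sigma_regular,sigma_irregular dosing-time jitter (hours, s.d.)
#'   for the two archetypes.
#' @param beta named numeric vector of log-odds coefficients linking static
#'   covariate z-scores (and the intervention arm indicator `group`) to the
#'   daily adherence probability.
#' @param survey_missing completely-at-random missingness rate for survey
#'   cells.
#' @param seed integer seed; identical params + seed give identical cohorts.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 32L,
                          n_days = 240L,
                          p_base = 0.75,
                          rho = 0.85,
                          delta_w = 0.10,
                          hawthorne_days = 30L,
                          hawthorne_boost = 0.3,
                          frac_irregular = 0.4,
                          sigma_regular = 0.35,
                          sigma_irregular = 2.5,
                          beta = c(adh_selfeff = 1.5, group = 0.4),
                          survey_missing = 0.05,
                          seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
            p_base = p_base, rho = rho, delta_w = delta_w,
            hawthorne_days = as.integer(hawthorne_days),
            hawthorne_boost = hawthorne_boost,
            frac_irregular = frac_irregular,
            sigma_regular = sigma_regular,
            sigma_irregular = sigma_irregular,
            beta = beta, survey_missing = survey_missing,
            seed = as.integer(seed))
  stopifnot(p$p_base > 0, p$p_base < 1, p$rho >= 0, p$rho <= 1,
            p$delta_w >= -1, p$delta_w <= 1, p$sigma_regular >= 0,
            p$sigma_irregular >= 0, p$frac_irregular >= 0,
            p$frac_irregular <= 1, p$survey_missing >= 0,
            p$survey_missing < 1, p$n_subjects >= 1, p$n_days >= 2)
  if (p$rho == 1 && (p$p_base %in% c(0, 1))) {
    adhera_log("degenerate chain: rho = 1 with deterministic base state")
  }
  class(p) <- c("cohort_params", "list")
  p
}

# Survey scales simulated per subject; adh_selfeff is the (optionally)
# planted covariate linked to adherence, the rest are distractors.
SYNTH_SCALES <- c("adh_selfeff", "perceived_stress", "social_support",
                  "symptom_burden", "med_beliefs", "mastery")

#' Generate a synthetic cohort
#'
#' @param params `cohort_params`.
#' @return list with `events` (`adhera_event_log`), `survey`
#'   (`adhera_survey`), and `truth` (per-subject latent states, archetypes,
#'   adherence probabilities and the planted parameters).
#' @export
generate_cohort <- function(params = cohort_params()) {
  p <- params
  with_seed(p$seed, {
    sids <- sprintf("S%03d", seq_len(p$n_subjects))
    group <- rep_len(c(1L, 0L), p$n_subjects)[sample.int(p$n_subjects)]
    z <- matrix(stats::rnorm(p$n_subjects * length(SYNTH_SCALES)),
                nrow = p$n_subjects,
                dimnames = list(sids, SYNTH_SCALES))
    irregular <- as.integer(stats::runif(p$n_subjects) < p$frac_irregular)
    mu_h <- sample(c(8, 9, 20, 21, 22), p$n_subjects, replace = TRUE) +
      stats::runif(p$n_subjects, -0.5, 0.5)
    sigma_h <- ifelse(irregular == 1L, p$sigma_irregular, p$sigma_regular)
    # subject-level adherence probability via logistic link
    off <- rep(0, p$n_subjects)
    for (nm in names(p$beta)) {
      off <- off + p$beta[[nm]] *
        (if (nm == "group") group else z[, nm])
    }
    p_adh <- stats::plogis(stats::qlogis(p$p_base) + off)
    start <- as.Date("2021-01-04") + sample.int(30L, p$n_subjects,
                                                replace = TRUE) - 1L
    states <- matrix(NA_integer_, p$n_subjects, p$n_days)
    ev_sid <- list(); ev_ts <- list()
    for (s in seq_len(p$n_subjects)) {
      dates <- start[s] + seq_len(p$n_days) - 1L
      wkend <- is_weekend_date(dates)
      miss <- 1 - p_adh[s]
      miss_t <- rep(miss, p$n_days)
      if (p$hawthorne_days > 0L) {
        hw <- seq_len(min(p$hawthorne_days, p$n_days))
        miss_t[hw] <- miss_t[hw] * p$hawthorne_boost
      }
      miss_t[wkend] <- miss_t[wkend] + p$delta_w
      miss_t <- pmin(pmax(miss_t, 0), 1)
      st <- integer(p$n_days)
      st[1L] <- stats::rbinom(1L, 1L, 1 - miss_t[1L])
      copy <- stats::runif(p$n_days) < p$rho
      fresh <- stats::rbinom(p$n_days, 1L, 1 - miss_t)
      for (t in 2:p$n_days) st[t] <- if (copy[t]) st[t - 1L] else fresh[t]
      states[s, ] <- st
      taken <- which(st == 1L)
      if (length(taken) > 0L) {
        hrs <- mu_h[s] + stats::rnorm(length(taken), 0, sigma_h[s])
        hrs <- pmin(pmax(hrs, 0), 23.983)  # truncate to [0, 24)
        ts <- as.POSIXct(paste(dates[taken], "00:00"), tz = "UTC") +
          round(hrs * 60) * 60
        ev_sid[[s]] <- rep(sids[s], length(taken))
        ev_ts[[s]] <- ts
      }
    }
    keep <- !vapply(ev_ts, is.null, logical(1L))
    if (!any(keep)) stop("generated cohort has no events at all",
                         call. = FALSE)
    events <- as_event_log(data.frame(
      subject_id = unlist(ev_sid[keep]),
      timestamp = .POSIXct(unlist(ev_ts[keep]), tz = "UTC")))
    # survey: three timepoints, scores = 3 + z + drift, MCAR missingness
    survey <- do.call(rbind, lapply(TIMEPOINTS, function(tp) {
      sc <- round(3 + z + matrix(stats::rnorm(length(z), 0, 0.2),
                                 nrow = nrow(z)), 2)
      df <- data.frame(subject_id = sids, timepoint = tp,
                       stringsAsFactors = FALSE)
      cbind(df, as.data.frame(sc))
    }))
    if (p$survey_missing > 0) {
      cells <- as.matrix(survey[SYNTH_SCALES])
      drop <- matrix(stats::runif(length(cells)) < p$survey_missing,
                     nrow = nrow(cells))
      cells[drop] <- NA_real_
      survey[SYNTH_SCALES] <- as.data.frame(cells)
    }
    survey$group <- group[match(survey$subject_id, sids)]
    survey <- survey[order(survey$subject_id, match(survey$timepoint,
                                                    TIMEPOINTS)), ]
    rownames(survey) <- NULL
    class(survey) <- c("adhera_survey", "data.frame")
    truth <- list(states = states, subject_id = sids, archetype = irregular,
                  p_adh = p_adh, mu_h = mu_h, sigma_h = sigma_h,
                  start_date = start, params = unclass(p))
    list(events = events, survey = survey, truth = truth)
  })
}

#' Recover the planted habit-persistence parameter
#'
#' Estimates the Markov persistence rho from daily taken/missed states by
#' pooling day-to-day state flips. Under the generator's chain (copy
#' yesterday w.p. rho, else redraw from the subject's adherence
#' probability p) the expected flip count over n transitions is
#' `n (1-rho) 2 p (1-p)`, which is exact at stationarity. The plug-in
#' `p-hat (1-p-hat)` denominator is corrected analytically for the
#' autocorrelation-inflated variance of the day-taken rate,
#' `E[p-hat(1-p-hat)] = p(1-p) [1 - (1+rho)/((1-rho) n)]`, and the
#' resulting equation is solved for rho by fixed-point iteration. Days
#' inside the initial monitoring-awareness window can be excluded since
#' the chain is not stationary there. Subjects frozen in one state
#' contribute neither flips nor denominator; a cohort with no state
#' variation at all pins rho at 1.
#'
#' @param daily `adhera_daily` records (the `has_event` column is the state
#'   proxy: an event exists iff the latent state is "taken").
#' @param exclude_first_days drop this many leading days per subject before
#'   estimating.
#' @param min_transitions minimum pooled transition count.
#' @return scalar estimate of rho in \[0, 1\].
#' @export
recover_persistence <- function(daily, exclude_first_days = 0,
                                min_transitions = 500L) {
  st <- do.call(rbind, lapply(split(daily, daily$subject_id), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    if (exclude_first_days > 0) {
      d <- d[d$date >= d$date[1L] + exclude_first_days, , drop = FALSE]
    }
    x <- d$has_event
    n <- length(x) - 1L
    if (n < 2L) return(c(flips = 0, n = 0, p = NA_real_))
    c(flips = sum(x[-1L] != x[-length(x)]), n = n, p = mean(x))
  }))
  st <- st[st[, "n"] > 0 & !is.na(st[, "p"]), , drop = FALSE]
  if (sum(st[, "n"]) < min_transitions) {
    stop("insufficient transitions for persistence recovery (",
         sum(st[, "n"]), " < ", min_transitions, ")", call. = FALSE)
  }
  rho <- 0.8
  for (it in 1:100) {
    corr <- pmax(1 - (1 + rho) / ((1 - rho + 1e-12) * st[, "n"]), 0.05)
    d <- st[, "p"] * (1 - st[, "p"]) / corr
    den <- sum(2 * st[, "n"] * d)
    if (den < 1e-9) return(1)  # no state variation anywhere: frozen cohort
    new <- min(max(1 - sum(st[, "flips"]) / den, 0), 1)
    if (abs(new - rho) < 1e-10) { rho <- new; break }
    rho <- new
  }
  rho
}

#' Weekend versus weekday miss rates
#'
#' Pooled empirical miss (no-event) rates on weekends and weekdays,
#' optionally excluding each subject's initial high-adherence window. Used
#' to verify that a planted weekend effect is recoverable.
#'
#' @inheritParams recover_persistence
#' @return named numeric vector `c(weekend, weekday)` of miss rates.
#' @export
miss_rates_by_daytype <- function(daily, exclude_first_days = 0) {
  d <- do.call(rbind, lapply(split(daily, daily$subject_id), function(di) {
    di <- di[order(di$date), , drop = FALSE]
    if (exclude_first_days > 0) {
      di <- di[di$date >= di$date[1L] + exclude_first_days, , drop = FALSE]
    }
    di
  }))
  c(weekend = mean(d$has_event[d$is_weekend == 1L] == 0L),
    weekday = mean(d$has_event[d$is_weekend == 0L] == 0L))
}
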