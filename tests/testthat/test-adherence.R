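test_that("epoch bins partition the clock with half-open boundaries", {
  expect_equal(assign_epoch(9.5), "Morning")
  expect_equal(assign_epoch(5 + 59 / 60), "Night")
  expect_equal(assign_epoch(12), "Afternoon")
  expect_equal(assign_epoch(c(0, 6, 18, 23.99)),
               c("Night", "Morning", "Evening", "Evening"))
  # partition: every minute of the day maps to exactly one epoch
  hours <- (0:1439) / 60
  ep <- assign_epoch(hours)
  expect_false(anyNA(ep))
  expect_equal(sort(unique(ep)),
               sort(c("Morning", "Afternoon", "Evening", "Night")))
})

test_that("observation-effect trimming removes early events and empty subjects", {
  log <- make_event_log("A", as.POSIXct("2021-01-01 09:00", tz = "UTC") +
                          c(0, 10, 35) * 86400)
  kept <- trim_hawthorne(log, 30)
  expect_equal(nrow(kept), 1L)
  expect_equal(as.Date(kept$timestamp, tz = "UTC"), as.Date("2021-02-05"))
  expect_equal(trim_hawthorne(log, 0), log)
  all_early <- make_event_log("B", as.POSIXct("2021-01-01 09:00",
                                              tz = "UTC") + c(0, 5) * 86400)
  expect_equal(nrow(trim_hawthorne(all_early, 30)), 0L)
})

test_that("daily labels implement the 24 +/- 6 h rule on the day of the later dose", {
  # Mon 20:00 -> Tue 21:00: 25 h, inside the window
  log <- make_event_log("A", c("2021-05-03 20:00", "2021-05-04 21:00"))
  d <- label_daily(log)
  expect_equal(nrow(d), 1L)
  expect_equal(d$inter_dose_hours, 25)
  expect_equal(d$is_adherent, 1L)
  expect_equal(d$epoch, "Evening")

  # Mon 20:00 -> Wed 09:00: Tue missed, Wed gap 37 h outside the window
  log <- make_event_log("A", c("2021-05-03 20:00", "2021-05-05 09:00"))
  d <- label_daily(log)
  expect_equal(d$has_event, c(0L, 1L))
  expect_equal(d$is_adherent, c(0L, 0L))
  expect_equal(d$inter_dose_hours[2], 37)
  expect_true(is.na(d$epoch[1]))

  # early double dose: 12 h gap is not adherent
  log <- make_event_log("A", c("2021-05-03 22:00", "2021-05-04 10:00"))
  d <- label_daily(log)
  expect_equal(d$is_adherent, 0L)
  expect_equal(d$inter_dose_hours, 12)

  # window endpoints are inclusive
  log <- make_event_log("A", c("2021-05-03 06:00", "2021-05-04 00:00",
                               "2021-05-05 06:00"))
  d <- label_daily(log)
  expect_equal(d$inter_dose_hours, c(18, 30))
  expect_equal(d$is_adherent, c(1L, 1L))

  expect_equal(nrow(label_daily(make_event_log(character(0), character(0)))),
               0L)
})

test_that("daily labeling matches the brute-force day-walk oracle on random streams", {
  set.seed(101)
  n_mismatch <- 0L
  for (r in 1:200) {
    ts <- random_event_stream(n_days = sample(10:40, 1L),
                              p_take = stats::runif(1, 0.4, 0.95),
                              p_double = stats::runif(1, 0, 0.3))
    if (length(ts) < 2L) next
    got <- label_daily(make_event_log("X", ts))
    want <- oracle_label_daily_one(ts)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
      next
    }
    expect_equal(got$date, want$date)
    n_mismatch <- n_mismatch +
      sum(got$has_event != want$has_event) +
      sum(got$is_adherent != want$is_adherent)
  }
  expect_equal(n_mismatch, 0L)
})

test_that("widening the window is monotone: labels only flip non-adherent -> adherent", {
  set.seed(77)
  for (r in 1:25) {
    ts <- random_event_stream(25)
    if (length(ts) < 2L) next
    narrow <- label_daily(make_event_log("X", ts), window = c(20, 28))
    wide <- label_daily(make_event_log("X", ts), window = c(16, 34))
    expect_true(all(wide$is_adherent >= narrow$is_adherent))
  }
})

test_that("weekly labels reduce daily labels by the >80% (>=6 of 7) rule", {
  mk_daily <- function(adh) {
    data.frame(subject_id = "A",
               date = as.Date("2021-05-03") + seq_along(adh) - 1L,
               has_event = adh, event_hour = ifelse(adh == 1L, 21, NA),
               inter_dose_hours = ifelse(adh == 1L, 24, NA),
               is_adherent = adh,
               epoch = ifelse(adh == 1L, "Evening", NA),
               is_weekend = as.integer(
                 as.POSIXlt(as.Date("2021-05-03") +
                              seq_along(adh) - 1L)$wday %in% c(0, 6)))
  }
  w6 <- label_weekly(mk_daily(c(1, 1, 1, 1, 1, 1, 0)))
  expect_equal(w6$n_adherent_days, 6L)
  expect_equal(w6$is_adherent_wk, 1L)
  w5 <- label_weekly(mk_daily(c(1, 1, 1, 1, 1, 0, 0)))
  expect_equal(w5$is_adherent_wk, 0L)
  # trailing partial week dropped; < 7 days gives no records
  expect_equal(nrow(label_weekly(mk_daily(rep(1, 13)))), 1L)
  expect_equal(nrow(label_weekly(mk_daily(rep(1, 6)))), 0L)
})

test_that("weekly time statistics and weekend levels follow their definitions", {
  d <- data.frame(subject_id = "A",
                  date = as.Date("2021-05-03") + 0:6,  # Mon..Sun
                  has_event = c(1, 1, 0, 0, 0, 1, 0),
                  event_hour = c(21, 23, NA, NA, NA, 9, NA),
                  inter_dose_hours = c(24, 26, NA, NA, NA, 30, NA),
                  is_adherent = c(1, 1, 0, 0, 0, 1, 0),
                  epoch = c("Evening", "Evening", NA, NA, NA, "Morning", NA),
                  is_weekend = c(0, 0, 0, 0, 0, 1, 1))
  w <- label_weekly(d)
  # Sat adherent, Sun missed
  expect_equal(w$weekend_adh_level, 50)
  expect_equal(w$modal_epoch, "Evening")
  expect_equal(w$time_mean, mean(c(21, 23, 9)))
  expect_equal(w$time_std, stats::sd(c(21, 23, 9)))

  # two events at 21:00 and 23:00 only
  d2 <- d
  d2$has_event <- c(1, 1, 0, 0, 0, 0, 0)
  d2$event_hour <- c(21, 23, NA, NA, NA, NA, NA)
  d2$is_adherent <- c(1, 1, 0, 0, 0, 0, 0)
  d2$epoch <- c("Evening", "Evening", NA, NA, NA, NA, NA)
  w2 <- label_weekly(d2)
  expect_equal(w2$time_mean, 22)
  expect_equal(w2$time_std, stats::sd(c(21, 23)), tolerance = 1e-12)
  expect_equal(w2$weekend_adh_level, 0)

  # single event week: sd defined as 0; zero-event week: absent
  d3 <- d2; d3$has_event <- c(1, 0, 0, 0, 0, 0, 0)
  d3$event_hour <- c(21, rep(NA, 6)); d3$is_adherent <- c(1, rep(0, 6))
  d3$epoch <- c("Evening", rep(NA, 6))
  expect_equal(label_weekly(d3)$time_std, 0)
  d4 <- d3; d4$has_event[1] <- 0; d4$event_hour[1] <- NA
  d4$is_adherent[1] <- 0; d4$epoch[1] <- NA
  w4 <- label_weekly(d4)
  expect_true(is.na(w4$time_mean) && is.na(w4$time_std) &&
                is.na(w4$modal_epoch))
})

test_that("weekly labeling equals the >=6-of-7 reduction on generated cohorts", {
  cohort <- tiny_cohort(n_subjects = 10, n_days = 100, seed = 3)
  daily <- cohort$labels$daily
  weekly <- cohort$labels$weekly
  for (sid in unique(weekly$subject_id)) {
    d <- daily[daily$subject_id == sid, ]
    d <- d[order(d$date), ]
    w <- weekly[weekly$subject_id == sid, ]
    for (k in seq_len(nrow(w))) {
      blk <- d$is_adherent[((k - 1) * 7 + 1):(k * 7)]
      expect_equal(w$is_adherent_wk[k], as.integer(sum(blk) >= 6))
      expect_equal(w$n_adherent_days[k], sum(blk))
    }
  }
})
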