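test_that("daily sample building counts, one-hots and weekend periodicity", {
  # 8 contiguous days, lag 7 -> exactly one sample
  d <- data.frame(subject_id = "A", date = as.Date("2021-05-04") + 0:7,
                  has_event = 1L, event_hour = 20.5,
                  inter_dose_hours = 24, is_adherent = 1L,
                  epoch = "Evening",
                  is_weekend = as.integer(as.POSIXlt(
                    as.Date("2021-05-04") + 0:7)$wday %in% c(0, 6)))
  s <- build_daily_samples(d, lag = 7)
  expect_equal(length(s$target), 1L)
  expect_equal(dim(s$dynamic), c(1L, 7L, 6L))
  # all 7 prior days adherent in the evening
  expect_true(all(s$dynamic[1, , "is_adherent"] == 1))
  expect_true(all(s$dynamic[1, , "Evening"] == 1))
  expect_true(all(s$dynamic[1, , c("Morning", "Afternoon", "Night")] == 0))
  # target day is Tue 2021-05-11; is_Weekend has 7-day periodicity:
  # lag-7 weekend flag equals the target day's own weekend status
  d2 <- d
  d2$date <- as.Date("2021-05-08") + 0:7  # target Sat 2021-05-15
  d2$is_weekend <- as.integer(as.POSIXlt(d2$date)$wday %in% c(0, 6))
  s2 <- build_daily_samples(d2, lag = 7)
  expect_equal(unname(s2$dynamic[1, 1, "is_Weekend"]), 1)  # oldest = t-7

  short <- d[1:5, ]
  short$subject_id <- "B"
  expect_warning(build_daily_samples(rbind(d, short), lag = 7), "skipped")
})

test_that("weekly samples carry one-hot and flagged time channels", {
  w <- data.frame(subject_id = "A", week_index = 1:5,
                  week_start = as.Date("2021-05-03") + (0:4) * 7,
                  n_adherent_days = c(7, 6, 2, 0, 7),
                  is_adherent_wk = c(1, 1, 0, 0, 1),
                  weekend_adh_level = c(100, 50, 0, 0, 100),
                  modal_epoch = c("Evening", "Evening", "Morning", NA,
                                  "Evening"),
                  time_mean = c(21, 20.5, 9, NA, 21.2),
                  time_std = c(0.3, 0.5, 1.1, NA, 0.2))
  s <- build_weekly_samples(w, lag = 4)
  expect_equal(length(s$target), 1L)
  expect_equal(dim(s$dynamic)[2:3], c(4L, 11L))
  expect_equal(s$target, 1L)
  # newest lag slice (t-1) is week 4: zero events -> imputation flag set
  expect_equal(unname(s$dynamic[1, 4, "time_imputed"]), 1)
  expect_true(is.na(s$dynamic[1, 4, "time_mean"]))
  # weekend_adh one-hots sum to 1 in every lag
  sums <- apply(s$dynamic[1, , c("weekend_adh_0", "weekend_adh_50",
                                 "weekend_adh_100")], 1, sum)
  expect_true(all(sums == 1))
  # t-4 was a fully adherent weekend
  expect_equal(unname(s$dynamic[1, 1, "weekend_adh_100"]), 1)
})

test_that("scale scoring sums, reverse-codes and errors on missing items", {
  sv <- data.frame(subject_id = c("A", "B"), timepoint = "baseline",
                   q1 = c(2, 4), q2 = c(3, 2), q3 = c(4, 5))
  scoring <- list(scales = list(total = list(items = c("q1", "q2", "q3"))))
  sc <- score_scales(sv, scoring)
  expect_equal(sc$total, c(9, 11))

  scoring_rev <- list(scales = list(total = list(
    items = c("q1", "q2", "q3"), reverse = "q1", range = c(1, 5))))
  sc2 <- score_scales(sv, scoring_rev)
  expect_equal(sc2$total[1], (1 + 5 - 2) + 3 + 4)

  scoring_bad <- list(scales = list(total = list(items = c("q1", "zz"))))
  expect_error(score_scales(sv, scoring_bad), "zz")

  # invariance to item column order
  sv_r <- sv[c("subject_id", "timepoint", "q3", "q1", "q2")]
  expect_equal(score_scales(sv_r, scoring)$total, sc$total)

  # mean aggregation
  scoring_m <- list(scales = list(avg = list(items = c("q1", "q2"),
                                             aggregate = "mean")))
  expect_equal(score_scales(sv, scoring_m)$avg, c(2.5, 3))
})

test_that("Cronbach's alpha matches closed forms and drops unreliable scales", {
  set.seed(5)
  x <- stats::rnorm(300)
  dup <- cbind(a = x, b = x)
  expect_equal(cronbach_alpha(dup), 1, tolerance = 1e-12)

  noise <- cbind(a = stats::rnorm(10000), b = stats::rnorm(10000))
  expect_lt(abs(cronbach_alpha(noise)), 0.05)

  # bivariate normal with covariance 0.5, unit variances: alpha -> 2/3
  n <- 50000
  z <- stats::rnorm(n)
  items <- cbind(a = sqrt(0.5) * z + sqrt(0.5) * stats::rnorm(n),
                 b = sqrt(0.5) * z + sqrt(0.5) * stats::rnorm(n))
  expect_equal(cronbach_alpha(items), 2 / 3, tolerance = 0.02)

  expect_warning(a0 <- cronbach_alpha(cbind(a = c(1, 2, 3),
                                            b = c(3, 2, 1))),
                 "undefined")
  expect_true(is.na(a0))

  # scoring integration: a scale of pure noise items is excluded at 0.7
  sv <- data.frame(subject_id = sprintf("S%02d", 1:40),
                   timepoint = "baseline",
                   n1 = stats::rnorm(40), n2 = stats::rnorm(40),
                   g1 = x[1:40], g2 = x[1:40] + stats::rnorm(40, 0, 0.1))
  scoring <- list(scales = list(
    noisy = list(items = c("n1", "n2")),
    good = list(items = c("g1", "g2"))))
  sc <- score_scales(sv, scoring, alpha_cutoff = 0.7)
  expect_false("noisy" %in% names(sc))
  expect_true("good" %in% names(sc))
})

test_that("availability filter applies >= threshold on training subjects only", {
  tab <- data.frame(subject_id = sprintf("S%d", 1:10),
                    half = c(rep(NA, 5), 1:5),         # 50% available
                    sixty = c(NA, NA, NA, NA, 1:6),    # 60% available
                    full = 1:10)
  out <- filter_availability(tab, 0.60)
  expect_false("half" %in% names(out))
  expect_true(all(c("sixty", "full") %in% names(out)))
  # availability computed on the training subjects only
  out2 <- filter_availability(tab, 0.60, train_subjects = sprintf("S%d", 6:10))
  expect_true("half" %in% names(out2))
  expect_error(filter_availability(data.frame(subject_id = "a",
                                              x = NA_real_), 0.6),
               "every feature")
  expect_error(filter_availability(tab, 0), "threshold")
})

test_that("iterative imputation recovers exact linear structure fit on train only", {
  set.seed(8)
  x <- stats::runif(40, 0, 10)
  train <- data.frame(x = x, y = 2 * x)
  train$y[7] <- NA
  out <- impute_static(train)
  expect_equal(out$train$y[7], 2 * x[7], tolerance = 1e-6)

  # categorical mode imputation + one-hot expansion
  train2 <- data.frame(num = c(1, 2, NA, 4, 5),
                       cat = c("A", "A", "A", "B", NA))
  out2 <- impute_static(train2)
  expect_false(any(is.na(out2$train)))
  expect_true("cat_B" %in% names(out2$train))
  expect_equal(out2$models$modes$cat, "A")

  # no missing values -> identity
  clean <- data.frame(a = 1:5, b = 6:10)
  expect_equal(impute_static(clean)$train, clean)

  # test set transformed with training-fitted imputer
  test <- data.frame(x = c(1, 3), y = c(NA, NA))
  out3 <- impute_static(train, test)
  expect_equal(out3$test$y, c(2, 6), tolerance = 1e-5)

  expect_error(impute_static(data.frame(a = c(NA_real_, NA_real_, NA_real_),
                                        b = c(1, 2, 3))),
               "entirely missing")
})

test_that("min-max scaling uses training bounds and handles constants", {
  sc <- scale_minmax(matrix(c(2, 4, 6), ncol = 1,
                            dimnames = list(NULL, "v")),
                     matrix(8, ncol = 1, dimnames = list(NULL, "v")))
  expect_equal(drop(sc$train), c(0, 0.5, 1))
  expect_equal(unname(drop(sc$test)), 1.5)
  expect_warning(sc2 <- scale_minmax(matrix(rep(3, 4), ncol = 1)),
                 "constant")
  expect_true(all(sc2$train == 0))
})

test_that("static alignment carries the latest completed timepoint forward", {
  static <- data.frame(subject_id = rep("A", 3),
                       timepoint = c("baseline", "month4", "month8"),
                       score = c(1, 2, 3))
  mk_samples <- function(dates) {
    d <- data.frame(subject_id = "A", date = dates, has_event = 1L,
                    event_hour = 20, inter_dose_hours = 24,
                    is_adherent = 1L, epoch = "Evening", is_weekend = 0L)
    structure(list(dynamic = array(0, c(length(dates), 1, 1),
                                   dimnames = list(NULL, NULL, "x")),
                   static = NULL, target = rep(1L, length(dates)),
                   subject = rep("A", length(dates)),
                   id = data.frame(subject_id = "A", date = dates),
                   channels = "x", lag = 1L, task = "daily"),
              class = "adhera_samples")
  }
  start <- c(A = as.Date("2021-01-01"))
  # month 5 target -> month-4 scores; month 2 target -> baseline
  s <- align_static(static, mk_samples(as.Date("2021-01-01") + c(150, 60)),
                    start)
  expect_equal(unname(drop(s$static)), c(2, 1))
  # missing month-4 row: baseline carried forward before month 8
  static2 <- static[c(1, 3), ]
  s2 <- align_static(static2, mk_samples(as.Date("2021-01-01") + 150), start)
  expect_equal(unname(drop(s2$static)), 1)
})

test_that("deleting the target day's event changes only the target, never features", {
  cohort <- tiny_cohort(n_subjects = 4, n_days = 80, seed = 21)
  daily <- cohort$labels$daily
  samp <- build_daily_samples(daily, lag = 7)
  # pick an event day target and erase its event
  k <- which(samp$target == 1L)[5]
  sid <- samp$subject[k]; dt <- samp$id$date[k]
  daily2 <- daily
  row <- which(daily2$subject_id == sid & daily2$date == dt)
  daily2[row, c("has_event", "is_adherent")] <- 0L
  daily2[row, c("event_hour", "inter_dose_hours")] <- NA_real_
  daily2[row, "epoch"] <- NA_character_
  samp2 <- build_daily_samples(daily2, lag = 7)
  k2 <- which(samp2$subject == sid & samp2$id$date == dt)
  expect_equal(samp2$dynamic[k2, , ], samp$dynamic[k, , ])
  expect_equal(samp2$target[k2], 0L)
})
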