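## Lagged dynamic feature tensors, survey scale scoring, and static-feature
## processing (availability filter, imputation, scaling, temporal join).

DAILY_CHANNELS <- c("is_adherent", "Morning", "Afternoon", "Evening",
                    "Night", "is_Weekend")
WEEKLY_CHANNELS <- c("is_adherent_wk", "weekend_adh_0", "weekend_adh_50",
                     "weekend_adh_100", "Morning", "Afternoon", "Evening",
                     "Night", "time_mean", "time_std", "time_imputed")

new_sample_set <- function(dynamic, static, target, subject, id, task) {
  structure(list(dynamic = dynamic, static = static,
                 target = as.integer(target), subject = subject, id = id,
                 channels = dimnames(dynamic)[[3L]],
                 lag = dim(dynamic)[2L], task = task),
            class = "adhera_samples")
}

#' @export
#' @method print adhera_samples
print.adhera_samples <- function(x, ...) {
  cat(sprintf("<adhera_samples: %d %s samples, %d lags x %d channels, %s>\n",
              length(x$target), x$task, x$lag, length(x$channels),
              if (is.null(x$static)) "no static block"
              else sprintf("%d static features", ncol(x$static))))
  invisible(x)
}

daily_channel_rows <- function(d) {
  ep <- outer(d$epoch, EPOCH_LEVELS, function(a, b) as.integer(!is.na(a) & a == b))
  cbind(is_adherent = d$is_adherent, ep, is_Weekend = d$is_weekend)
}

weekly_channel_rows <- function(w) {
  wa <- outer(w$weekend_adh_level, c(0, 50, 100),
              function(a, b) as.integer(a == b))
  ep <- outer(w$modal_epoch, EPOCH_LEVELS,
              function(a, b) as.integer(!is.na(a) & a == b))
  cbind(is_adherent_wk = w$is_adherent_wk, wa, ep,
        time_mean = w$time_mean, time_std = w$time_std,
        time_imputed = as.integer(is.na(w$time_mean)))
}

build_lagged <- function(records, lag, channel_fun, channels, target_col,
                         id_cols, task) {
  parts <- split(records, records$subject_id)
  dyn <- list(); tgt <- list(); ids <- list()
  for (sid in names(parts)) {
    r <- parts[[sid]]
    n <- nrow(r)
    if (n < lag + 1L) {
      warning("subject ", sid, " has ", n, " records (< lag+1 = ", lag + 1L,
              "); skipped", call. = FALSE)
      next
    }
    ch <- channel_fun(r)  # n x C
    t_idx <- (lag + 1L):n
    # slice j of the lag axis = lag (lag+1-j) days/weeks back, oldest first
    a <- array(NA_real_, c(length(t_idx), lag, length(channels)),
               dimnames = list(NULL, NULL, channels))
    for (j in seq_len(lag)) a[, j, ] <- ch[t_idx - (lag + 1L - j), ,
                                           drop = FALSE]
    dyn[[sid]] <- a
    tgt[[sid]] <- r[[target_col]][t_idx]
    ids[[sid]] <- cbind(data.frame(subject_id = sid,
                                   stringsAsFactors = FALSE),
                        r[t_idx, id_cols, drop = FALSE])
  }
  if (length(dyn) == 0L) stop("no subject has enough records", call. = FALSE)
  n_tot <- sum(vapply(dyn, function(a) dim(a)[1L], integer(1L)))
  dynamic <- array(NA_real_, c(n_tot, lag, length(channels)),
                   dimnames = list(NULL, NULL, channels))
  at <- 1L
  for (a in dyn) {
    k <- dim(a)[1L]
    dynamic[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  id <- do.call(rbind, ids)
  rownames(id) <- NULL
  new_sample_set(dynamic, NULL, unlist(tgt, use.names = FALSE),
                 id$subject_id, id, task)
}

#' Build daily prediction samples
#'
#' One sample per subject-day with a full lag window of prior days. Each of
#' the `lag` time steps carries six channels: yesterday's (etc.) adherence
#' flag, the four dosing-epoch one-hots, and the weekend flag. The target
#' is the day's own adherence label; the target day's event information
#' never enters the features.
#'
#' @param daily `adhera_daily` records, contiguous per subject.
#' @param lag number of lagged days (default 7).
#' @return `adhera_samples` with a `n x lag x 6` dynamic tensor; lag axis
#'   ordered oldest to newest.
#' @export
build_daily_samples <- function(daily, lag = 7L) {
  build_lagged(daily, as.integer(lag), daily_channel_rows, DAILY_CHANNELS,
               "is_adherent", "date", "daily")
}

#' Build weekly prediction samples
#'
#' One sample per subject-week with a full lag window of prior weeks. Each
#' time step carries the weekly adherence flag, weekend-adherence-level
#' one-hots (0/50/100), modal-epoch one-hots, the mean and standard
#' deviation of the dosing hour, and an indicator flagging zero-event weeks
#' whose time statistics are absent (left `NA` here; filled with
#' training-set channel means when a model is fitted).
#'
#' @param weekly `adhera_weekly` records, consecutive per subject.
#' @param lag number of lagged weeks (default 4).
#' @return `adhera_samples` with a `n x lag x 11` dynamic tensor.
#' @export
build_weekly_samples <- function(weekly, lag = 4L) {
  id_cols <- intersect(c("week_index", "week_start"), names(weekly))
  build_lagged(weekly, as.integer(lag), weekly_channel_rows, WEEKLY_CHANNELS,
               "is_adherent_wk", id_cols, "weekly")
}

#' Score survey scales from item-level responses
#'
#' Config-driven sum/mean scoring with reverse coding. Each scale names its
#' items, the items to reverse-code, the item response range, and the
#' aggregation. Reverse coding maps x to (max + min - x) on the stated
#' range before aggregation. A missing item response propagates to a
#' missing scale score (imputation is a later, fit-on-train step). Scales
#' failing an internal-consistency cutoff (Cronbach's alpha) can be dropped
#' here.
#'
#' @param survey `adhera_survey` with item-level columns.
#' @param scoring list: `scales` = named list, each with `items`
#'   (character), optional `reverse` (character subset), `range`
#'   (length-2 numeric, required when `reverse` is non-empty), and
#'   `aggregate` ("sum" or "mean", default "sum").
#' @param alpha_cutoff if non-NULL, drop scales with Cronbach's alpha below
#'   this value (computed on pooled complete cases).
#' @return data.frame `subject_id`, `timepoint`, one column per retained
#'   scale.
#' @export
score_scales <- function(survey, scoring, alpha_cutoff = NULL) {
  stopifnot(is.list(scoring), is.list(scoring$scales))
  out <- survey[c("subject_id", "timepoint")]
  for (nm in names(scoring$scales)) {
    sc <- scoring$scales[[nm]]
    missing_items <- setdiff(sc$items, names(survey))
    if (length(missing_items) > 0L) {
      stop("scale '", nm, "': item(s) not in survey table: ",
           paste(missing_items, collapse = ", "), call. = FALSE)
    }
    items <- as.matrix(survey[sc$items])
    rev_items <- intersect(sc$reverse %||% character(), sc$items)
    if (length(rev_items) > 0L) {
      if (is.null(sc$range) || length(sc$range) != 2L) {
        stop("scale '", nm, "' has reverse-coded items but no range",
             call. = FALSE)
      }
      items[, rev_items] <- sum(sc$range) - items[, rev_items]
    }
    if (!is.null(alpha_cutoff)) {
      a <- tryCatch(cronbach_alpha(items), error = function(e) NA_real_,
                    warning = function(w) NA_real_)
      if (is.na(a) || a < alpha_cutoff) {
        adhera_log("scale '", nm, "' dropped: Cronbach's alpha ",
                   ifelse(is.na(a), "undefined", sprintf("%.3f", a)),
                   " below cutoff ", alpha_cutoff)
        next
      }
    }
    agg <- sc$aggregate %||% "sum"
    out[[nm]] <- switch(agg,
                        sum = rowSums(items),
                        mean = rowMeans(items),
                        stop("unknown aggregate '", agg, "'", call. = FALSE))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`
#' computed on complete cases.
#'
#' @param items numeric matrix or data.frame, one column per item.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2L) stop("cronbach_alpha needs >= 2 items", call. = FALSE)
  if (nrow(m) < 3L) stop("cronbach_alpha needs >= 3 complete cases",
                         call. = FALSE)
  vt <- stats::var(rowSums(m))
  if (vt < 1e-12) {
    warning("zero total-score variance: alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / vt)
}

#' Filter static features by availability
#'
#' Drops feature columns whose non-missing fraction, computed on training
#' subjects only, falls below the threshold (boundary kept: >= threshold
#' survives).
#'
#' @param table data.frame with `subject_id` and feature columns (plus
#'   optionally `timepoint`).
#' @param threshold minimum non-missing fraction in (0, 1\].
#' @param train_subjects subjects over which availability is computed;
#'   default all.
#' @return the table with failing columns removed.
#' @export
filter_availability <- function(table, threshold = 0.60,
                                train_subjects = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  meta <- intersect(c("subject_id", "timepoint"), names(table))
  feats <- setdiff(names(table), meta)
  rows <- if (is.null(train_subjects)) rep(TRUE, nrow(table))
          else table$subject_id %in% train_subjects
  avail <- vapply(table[rows, feats, drop = FALSE],
                  function(x) mean(!is.na(x)), numeric(1L))
  drop <- names(avail)[avail < threshold]
  if (length(drop) == length(feats)) {
    stop("availability filter would drop every feature", call. = FALSE)
  }
  if (length(drop) > 0L) {
    adhera_log("availability filter dropped: ", paste(drop, collapse = ", "))
  }
  table[c(meta, setdiff(feats, drop))]
}

#' Fit-on-train iterative imputation of static features
#'
#' Numeric columns are filled by round-robin regression imputation: after a
#' mean initialization, each incomplete column is repeatedly re-estimated
#' by least squares from all other columns, using models fitted on
#' training rows only. Categorical (character/factor) columns are filled
#' with the training mode and expanded to indicator columns. The test
#' table, if given, is transformed with the training-fitted models.
#'
#' @param train data.frame of features (plus optional `subject_id` /
#'   `timepoint` metadata columns, which pass through untouched).
#' @param test optional data.frame with the same columns.
#' @param max_iter round-robin sweeps.
#' @return list with `train`, `test` (or NULL), and `models` (the fitted
#'   imputer, reusable via its structure).
#' @export
impute_static <- function(train, test = NULL, max_iter = 10L) {
  meta <- intersect(c("subject_id", "timepoint"), names(train))
  feats <- setdiff(names(train), meta)
  is_cat <- vapply(train[feats], function(x) is.character(x) || is.factor(x),
                   logical(1L))
  entirely_missing <- feats[vapply(train[feats],
                                   function(x) all(is.na(x)), logical(1L))]
  if (length(entirely_missing) > 0L) {
    stop("column(s) entirely missing in training data (should have been ",
         "filtered): ", paste(entirely_missing, collapse = ", "),
         call. = FALSE)
  }
  cat_cols <- feats[is_cat]; num_cols <- feats[!is_cat]
  modes <- lapply(train[cat_cols], function(x) {
    tx <- table(x[!is.na(x)])
    names(tx)[which.max(tx)]
  })
  fill_cat <- function(df) {
    for (cc in cat_cols) df[[cc]][is.na(df[[cc]])] <- modes[[cc]]
    df
  }
  train <- fill_cat(train)
  if (!is.null(test)) test <- fill_cat(test)

  col_means <- vapply(train[num_cols], function(x) mean(x, na.rm = TRUE),
                      numeric(1L))
  betas <- list()
  if (length(num_cols) > 0L) {
    X <- as.matrix(train[num_cols])
    miss <- is.na(X)
    Xf <- X
    for (j in seq_along(num_cols)) Xf[miss[, j], j] <- col_means[j]
    incomplete <- num_cols[colSums(miss) > 0L]
    if (length(incomplete) > 0L && length(num_cols) > 1L) {
      for (it in seq_len(max_iter)) {
        for (cc in incomplete) {
          j <- match(cc, num_cols)
          obs <- !miss[, j]
          Z <- cbind(1, Xf[, -j, drop = FALSE])
          fit <- stats::lm.fit(Z[obs, , drop = FALSE], X[obs, j])
          b <- fit$coefficients
          b[is.na(b)] <- 0
          betas[[cc]] <- b
          Xf[miss[, j], j] <- (Z %*% b)[miss[, j]]
        }
      }
    }
    train[num_cols] <- as.data.frame(Xf)
  }
  apply_to <- function(df) {
    if (is.null(df) || length(num_cols) == 0L) return(df)
    X <- as.matrix(df[num_cols])
    miss <- is.na(X)
    Xf <- X
    for (j in seq_along(num_cols)) Xf[miss[, j], j] <- col_means[j]
    for (it in seq_len(max_iter)) {
      for (cc in names(betas)) {
        j <- match(cc, num_cols)
        if (!any(miss[, j])) next
        Z <- cbind(1, Xf[, -j, drop = FALSE])
        Xf[miss[, j], j] <- (Z %*% betas[[cc]])[miss[, j]]
      }
    }
    df[num_cols] <- as.data.frame(Xf)
    df
  }
  test <- apply_to(test)
  onehot <- function(df) {
    if (is.null(df) || length(cat_cols) == 0L) return(df)
    for (cc in cat_cols) {
      lev <- sort(unique(train[[cc]]))
      for (lv in lev[-1L]) {  # first level is the reference
        df[[paste0(cc, "_", lv)]] <- as.integer(df[[cc]] == lv)
      }
      df[[cc]] <- NULL
    }
    df
  }
  list(train = onehot(train), test = onehot(test),
       models = list(col_means = col_means, betas = betas, modes = modes,
                     cat_cols = cat_cols, num_cols = num_cols))
}

#' Min-max scaling fitted on training data
#'
#' Affinely maps each numeric feature so the training minimum goes to 0 and
#' the training maximum to 1; test values use the training bounds and may
#' fall outside \[0, 1\]. Constant training columns map to 0 with a
#' warning.
#'
#' @param train numeric matrix or data.frame.
#' @param test optional matrix/data.frame with the same columns.
#' @return list with `train`, `test` (or NULL), `min`, `max`.
#' @export
scale_minmax <- function(train, test = NULL) {
  tr <- as.matrix(train)
  lo <- apply(tr, 2L, min)
  hi <- apply(tr, 2L, max)
  const <- hi - lo < 1e-12
  if (any(const)) {
    warning("constant training column(s) mapped to 0: ",
            paste(colnames(tr)[const], collapse = ", "), call. = FALSE)
  }
  rng <- ifelse(const, 1, hi - lo)
  tf <- function(m) {
    m <- as.matrix(m)
    out <- sweep(sweep(m, 2L, lo, "-"), 2L, rng, "/")
    out[, const] <- 0
    out
  }
  list(train = tf(tr), test = if (is.null(test)) NULL else tf(test),
       min = lo, max = hi)
}

TIMEPOINT_OFFSET_DAYS <- c(baseline = 0, month4 = 122, month8 = 244)

#' Align static features to prediction samples
#'
#' Each sample receives the scores from the most recent survey timepoint
#' completed at or before its target date (last observation carried
#' forward); targets before the 4-month follow-up use baseline scores.
#' Subjects with no completed timepoint are excluded.
#'
#' @param static data.frame with `subject_id`, `timepoint`, feature
#'   columns.
#' @param samples `adhera_samples` whose `id` carries a `date` (daily) or
#'   `week_start` (weekly) column.
#' @param start_dates named Date vector: each subject's day-0 (start of
#'   monitoring), anchoring the 0/4/8-month timepoints.
#' @return the `adhera_samples` with its `static` matrix populated (samples
#'   from subjects lacking any completed timepoint are dropped).
#' @export
align_static <- function(static, samples, start_dates) {
  date_col <- if ("date" %in% names(samples$id)) "date" else "week_start"
  stopifnot(date_col %in% names(samples$id))
  feats <- setdiff(names(static), c("subject_id", "timepoint"))
  completed <- static[rowSums(!is.na(static[feats])) > 0L, , drop = FALSE]
  n <- length(samples$target)
  rows <- integer(n)
  for (k in seq_len(n)) {
    sid <- samples$subject[k]
    cand <- completed[completed$subject_id == sid, , drop = FALSE]
    if (nrow(cand) == 0L) { rows[k] <- NA_integer_; next }
    elapsed <- as.numeric(samples$id[[date_col]][k] - start_dates[[sid]])
    off <- TIMEPOINT_OFFSET_DAYS[cand$timepoint]
    ok <- which(off <= elapsed)
    pick <- if (length(ok) > 0L) ok[which.max(off[ok])] else which.min(off)
    rows[k] <- which(static$subject_id == sid &
                       static$timepoint == cand$timepoint[pick])[1L]
  }
  keep <- !is.na(rows)
  if (!all(keep)) {
    adhera_log("align_static dropped ", sum(!keep),
               " sample(s) from subjects with no completed timepoint")
  }
  static_m <- as.matrix(static[rows[keep], feats, drop = FALSE])
  rownames(static_m) <- NULL
  out <- samples
  out$dynamic <- samples$dynamic[keep, , , drop = FALSE]
  out$target <- samples$target[keep]
  out$subject <- samples$subject[keep]
  out$id <- samples$id[keep, , drop = FALSE]
  out$static <- static_m
  out
}
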