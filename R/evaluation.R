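## Leakage-safe subject-level nested cross-validation: preprocessing and
## resampling fitted per training fold, L1 feature selection with lag
## expansion, inner-fold hyperparameter tuning, and confusion-based metrics.

#' Plan subject-level cross-validation folds
#'
#' Subjects are shuffled with the seed and partitioned into `k` near-equal
#' test sets; each subject appears in exactly one test set, so no subject
#' ever contributes rows to both sides of a fold.
#'
#' @param subjects character vector of subject ids (duplicates allowed).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return `adhera_fold_plan`: list of `k` folds, each with `$train` and
#'   `$test` subject sets.
#' @export
plan_folds <- function(subjects, k = 5L, seed = 1L) {
  ids <- unique(subjects)
  if (k > length(ids)) {
    stop("k = ", k, " exceeds the number of subjects (", length(ids), ")",
         call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(ids))
  sizes <- rep(length(ids) %/% k, k)
  extra <- length(ids) %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  folds <- lapply(seq_len(k), function(i) {
    test <- shuffled[starts[i]:stops[i]]
    list(train = setdiff(ids, test), test = test)
  })
  structure(list(folds = folds, k = k, seed = seed),
            class = "adhera_fold_plan")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and specificity as percentages, with the
#' adherent class (1) as positive. Specificity therefore measures how well
#' non-adherence — the clinically critical minority — is detected.
#' Undefined ratios (zero denominator) are reported as `NA`, never 0.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return named list of percentages plus the counts.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  stopifnot(n >= 1L)
  ratio <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
  list(accuracy = 100 * (tp + tn) / n,
       precision = ratio(tp, tp + fp),
       recall = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

confusion_counts <- function(y, pred) {
  list(tp = sum(y == 1L & pred == 1L), fp = sum(y == 0L & pred == 1L),
       tn = sum(y == 0L & pred == 0L), fn = sum(y == 1L & pred == 0L))
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a training set by interpolating synthetic minority rows: each
#' synthetic sample lies on the segment between a random minority row and
#' one of its k nearest minority neighbors, so every synthetic row stays
#' within the minority bounding box. Applied strictly inside training
#' folds; test class ratios are never altered.
#'
#' @param x flattened feature matrix (training rows only).
#' @param y 0/1 targets.
#' @param seed sampling seed.
#' @param k neighbor count; reduced with a warning when the minority class
#'   is smaller than `k + 1`.
#' @return list with balanced `x` and `y` (original rows first).
#' @export
apply_smote <- function(x, y, seed = 1L, k = 5L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  tab <- table(factor(y, levels = c(0, 1)))
  if (tab[1L] == tab[2L]) return(list(x = x, y = y))
  minority <- as.integer(names(tab)[which.min(tab)])
  need <- abs(diff(as.integer(tab)))
  mi <- which(y == minority)
  if (length(mi) < 2L) stop("SMOTE needs >= 2 minority samples",
                            call. = FALSE)
  if (length(mi) < k + 1L) {
    k <- length(mi) - 1L
    warning("minority class smaller than k+1; using k = ", k, call. = FALSE)
  }
  xm <- x[mi, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  with_seed(seed, {
    base_ix <- sample.int(nrow(xm), need, replace = TRUE)
    nb_ix <- nn[cbind(base_ix, sample.int(k, need, replace = TRUE))]
    u <- stats::runif(need)
    synth <- xm[base_ix, , drop = FALSE] +
      u * (xm[nb_ix, , drop = FALSE] - xm[base_ix, , drop = FALSE])
    list(x = rbind(x, synth), y = c(y, rep(minority, need)))
  })
}

#' Model-based feature selection with lag expansion
#'
#' Fits an L1-penalized logistic model on the flattened training matrix
#' (penalty chosen by internal cross-validation) and keeps features with
#' nonzero coefficients. Because the recurrent branch needs a rectangular
#' tensor, any dynamic channel selected at one or more lags is then
#' retained at *all* lags; static features are kept iff selected. An empty
#' selection falls back to all features with a warning.
#'
#' @param flat list from [flatten_samples()] (training fold only, typically
#'   after SMOTE).
#' @param seed fold-assignment seed for the internal `cv.glmnet`.
#' @return list with `channels`, `static`, and `columns` (flattened names
#'   in original order).
#' @export
select_features <- function(flat, seed = 1L) {
  x <- flat$x; y <- flat$y
  keep_raw <- tryCatch({
    foldid <- with_seed(seed, sample(rep_len(1:3, nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            foldid = foldid)
    cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
    rownames(cf)[-1L][cf[-1L, 1L] != 0]
  }, error = function(e) character())
  layout <- flat$layout
  dyn_cols <- as.vector(vapply(seq_len(layout$lag), function(lb)
    paste0("lag", lb, "_", layout$channels), character(length(layout$channels))))
  sel_dyn <- intersect(keep_raw, dyn_cols)
  sel_static <- intersect(keep_raw, layout$static %||% character())
  sel_channels <- unique(sub("^lag[0-9]+_", "", sel_dyn))
  if (length(sel_channels) == 0L && length(sel_static) == 0L) {
    warning("empty feature selection; keeping all features", call. = FALSE)
    sel_channels <- layout$channels
    sel_static <- layout$static %||% character()
  }
  sel_channels <- layout$channels[layout$channels %in% sel_channels]
  sel_static <- (layout$static %||% character())[
    (layout$static %||% character()) %in% sel_static]
  columns <- c(as.vector(vapply(seq_len(layout$lag), function(lb)
    paste0("lag", lb, "_", sel_channels), character(length(sel_channels)))),
    sel_static)
  list(channels = sel_channels, static = sel_static, columns = columns)
}

subset_sample_features <- function(samples, channels, static) {
  out <- samples
  out$dynamic <- samples$dynamic[, , channels, drop = FALSE]
  out$channels <- channels
  if (!is.null(samples$static) && length(static) > 0L) {
    out$static <- samples$static[, static, drop = FALSE]
  } else {
    out$static <- NULL
  }
  out
}

subset_sample_rows <- function(samples, idx) {
  out <- samples
  out$dynamic <- samples$dynamic[idx, , , drop = FALSE]
  out$static <- if (!is.null(samples$static))
    samples$static[idx, , drop = FALSE]
  out$target <- samples$target[idx]
  out$subject <- samples$subject[idx]
  out$id <- samples$id[idx, , drop = FALSE]
  out
}

CONTINUOUS_CHANNELS <- c("time_mean", "time_std")

# Fit-on-train preprocessing of a sample pair: fill absent weekly time
# statistics with training channel means, min-max scale continuous dynamic
# channels, and impute + scale the static block.
preprocess_fold <- function(train_s, test_s = NULL) {
  cont <- intersect(CONTINUOUS_CHANNELS, train_s$channels)
  prep <- list(cont = cont)
  for (ch in cont) {
    v <- train_s$dynamic[, , ch]
    mu <- mean(v, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    train_s$dynamic[, , ch][is.na(train_s$dynamic[, , ch])] <- mu
    lo <- min(train_s$dynamic[, , ch]); hi <- max(train_s$dynamic[, , ch])
    rng <- if (hi - lo < 1e-12) 1 else hi - lo
    train_s$dynamic[, , ch] <- (train_s$dynamic[, , ch] - lo) / rng
    if (!is.null(test_s)) {
      test_s$dynamic[, , ch][is.na(test_s$dynamic[, , ch])] <- mu
      test_s$dynamic[, , ch] <- (test_s$dynamic[, , ch] - lo) / rng
    }
    prep[[ch]] <- c(mean = mu, lo = lo, rng = rng)
  }
  if (!is.null(train_s$static)) {
    tr_df <- as.data.frame(train_s$static)
    te_df <- if (!is.null(test_s)) as.data.frame(test_s$static)
    imp <- impute_static(tr_df, te_df)
    sc <- suppressWarnings(scale_minmax(imp$train, imp$test))
    train_s$static <- sc$train
    if (!is.null(test_s)) test_s$static <- sc$test
  }
  list(train = train_s, test = test_s, prep = prep)
}

canonical_model_kind <- function(kind) {
  aliases <- c(rf = "random_forest", gbt = "gradient_boosted_trees",
               lr = "logistic_regression", xgb = "gradient_boosted_trees")
  kind <- ifelse(kind %in% names(aliases), aliases[kind], kind)
  bad <- setdiff(kind, c("fusion", BASELINE_KINDS))
  if (length(bad) > 0L) stop("unknown model kind(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  unname(kind)
}

expand_grid_list <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  multi <- grid[vapply(grid, length, integer(1L)) > 1L]
  if (length(multi) == 0L) return(list(grid))
  combos <- expand.grid(multi, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    utils::modifyList(grid, as.list(combos[i, , drop = FALSE]))
  })
}

make_model <- function(kind, combo, config, seed) {
  if (kind == "fusion") {
    args <- utils::modifyList(config$fusion, combo)
    args <- args[intersect(names(args), names(formals(fusion_config)))]
    args$seed <- seed
    cfg <- do.call(fusion_config, args)
    list(kind = "fusion", fusion_cfg = cfg)
  } else {
    list(kind = kind, hyper = combo)
  }
}

fit_model_on <- function(spec, train_s, flat_train, seed) {
  if (spec$kind == "fusion") {
    m <- build_fusion(spec$fusion_cfg, dim(train_s$dynamic)[2L],
                      dim(train_s$dynamic)[3L],
                      if (is.null(train_s$static)) 0L else ncol(train_s$static),
                      channels = train_s$channels,
                      static_names = colnames(train_s$static))
    train_model(m, train_s)
  } else {
    m <- build_baseline(spec$kind, spec$hyper, seed = seed)
    train_model(m, flat_train)
  }
}

predict_on <- function(model, test_s, flat_test) {
  if (model$kind == "fusion") predict_proba(model, test_s)
  else predict_proba(model, flat_test)
}

# Resample a training fold with SMOTE on the flattened representation and
# re-inflate for the recurrent branch.
smote_fold <- function(train_s, seed) {
  flat <- flatten_samples(train_s)
  res <- apply_smote(flat$x, flat$y, seed = seed)
  tensor <- unflatten_matrix(res$x, res$y, flat$layout,
                             subject = c(flat$subject,
                                         rep("synthetic",
                                             length(res$y) - length(flat$y))))
  tensor$channels <- train_s$channels
  list(samples = tensor, flat = list(x = res$x, y = res$y,
                                     layout = flat$layout))
}

#' Run leakage-safe nested cross-validation
#'
#' For each outer fold (subject-level split): imputation, scaling, SMOTE
#' and feature selection are fitted on the training subjects only; an
#' inner subject-level grid search picks hyperparameters when a grid has
#' more than one combination; the tuned model is refitted on the full
#' training fold and evaluated once on the untouched test fold. Metrics
#' are aggregated as mean and standard deviation over folds. Disjointness
#' of train and test subjects is asserted at every fit.
#'
#' @param samples `adhera_samples` (with static block attached if the
#'   models should use one).
#' @param models character vector of model kinds (aliases rf/svm/gbt/lr
#'   accepted).
#' @param config `adhera_config`.
#' @param permute_targets if TRUE, targets are randomly permuted before
#'   the run (permutation-null check).
#' @return `adhera_cv_report`.
#' @export
run_nested_cv <- function(samples, models = c("fusion",
                                              "logistic_regression"),
                          config = default_config(),
                          permute_targets = FALSE) {
  models <- canonical_model_kind(models)
  if (permute_targets) {
    samples$target <- with_seed(derive_seed(config$seed, "permute"),
                                sample(samples$target))
  }
  plan <- plan_folds(samples$subject, config$cv_folds,
                     derive_seed(config$seed, "folds"))
  fold_results <- list()
  audits <- list()
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    assert_disjoint_subjects(fold$train, fold$test, "fold plan")
    tr <- subset_sample_rows(samples, samples$subject %in% fold$train)
    te <- subset_sample_rows(samples, samples$subject %in% fold$test)
    assert_disjoint_subjects(tr$subject, fold$test, "training rows")
    pp <- preprocess_fold(tr, te)
    tr <- pp$train; te <- pp$test
    sm <- smote_fold(tr, derive_seed(config$seed, paste0("smote", fi)))
    sel <- select_features(sm$flat,
                           derive_seed(config$seed, paste0("select", fi)))
    tr_sel <- subset_sample_features(sm$samples, sel$channels, sel$static)
    te_sel <- subset_sample_features(te, sel$channels, sel$static)
    flat_tr <- flatten_samples(tr_sel)
    flat_te <- flatten_samples(te_sel)
    flat_te$x <- flat_te$x[, colnames(flat_tr$x), drop = FALSE]
    fold_seed <- derive_seed(config$seed, paste0("fit", fi))
    for (kind in models) {
      grid <- if (kind == "fusion") config$fusion
              else config$baselines[[kind]] %||% list()
      combos <- expand_grid_list(grid)
      chosen <- combos[[1L]]
      if (length(combos) > 1L) {
        chosen <- tune_inner(kind, combos, tr, fold, config, fi)
      }
      spec <- make_model(kind, chosen, config, fold_seed)
      fitted <- fit_model_on(spec, tr_sel, flat_tr, fold_seed)
      prob <- predict_on(fitted, te_sel, flat_te)
      pred <- as.integer(prob >= 0.5)
      cc <- confusion_counts(te_sel$target, pred)
      met <- do.call(compute_metrics, cc)
      fold_results[[length(fold_results) + 1L]] <-
        c(list(model = kind, fold = fi), met,
          list(chosen = chosen, n_test = length(pred)))
    }
    audits[[fi]] <- list(
      fold = fi,
      train_subjects = fold$train, test_subjects = fold$test,
      smote_class_counts = as.list(table(factor(sm$flat$y,
                                                levels = c(0, 1)))),
      test_class_counts = as.list(table(factor(te_sel$target,
                                               levels = c(0, 1)))),
      selected_channels = sel$channels, selected_static = sel$static)
  }
  build_cv_report(fold_results, audits, plan, models, samples, config)
}

# Inner subject-level grid search on the outer training fold.
tune_inner <- function(kind, combos, tr, fold, config, fold_index) {
  k_in <- min(3L, length(fold$train))
  inner <- plan_folds(tr$subject, k_in,
                      derive_seed(config$seed, paste0("inner", fold_index)))
  acc <- vapply(combos, function(combo) {
    accs <- vapply(inner$folds, function(inf) {
      itr <- subset_sample_rows(tr, tr$subject %in% inf$train)
      ite <- subset_sample_rows(tr, tr$subject %in% inf$test)
      assert_disjoint_subjects(itr$subject, inf$test, "inner fold")
      ism <- smote_fold(itr, derive_seed(config$seed, "inner_smote"))
      ifl <- flatten_samples(ism$samples)
      spec <- make_model(kind, combo, config,
                         derive_seed(config$seed, "inner_fit"))
      fitted <- fit_model_on(spec, ism$samples, ifl,
                             derive_seed(config$seed, "inner_fit"))
      ite_flat <- flatten_samples(ite)
      prob <- predict_on(fitted, ite, ite_flat)
      mean((prob >= 0.5) == ite$target)
    }, numeric(1L))
    mean(accs)
  }, numeric(1L))
  combos[[which.max(acc)]]
}

METRIC_NAMES <- c("accuracy", "precision", "recall", "specificity")

build_cv_report <- function(fold_results, audits, plan, models, samples,
                            config) {
  df <- do.call(rbind, lapply(fold_results, function(r) {
    data.frame(model = r$model, fold = r$fold, accuracy = r$accuracy,
               precision = r$precision, recall = r$recall,
               specificity = r$specificity, tp = r$tp, fp = r$fp,
               tn = r$tn, fn = r$fn, n_test = r$n_test,
               stringsAsFactors = FALSE)
  }))
  summ <- lapply(stats::setNames(models, models), function(m) {
    sub <- df[df$model == m, , drop = FALSE]
    list(mean = vapply(METRIC_NAMES,
                       function(cn) mean(sub[[cn]], na.rm = TRUE),
                       numeric(1L)),
         sd = vapply(METRIC_NAMES,
                     function(cn) stats::sd(sub[[cn]]), numeric(1L)))
  })
  maj <- 100 * max(mean(samples$target), 1 - mean(samples$target))
  structure(list(task = samples$task, folds = df, summary = summ,
                 majority_rate = maj, audits = audits,
                 plan = list(k = plan$k, seed = plan$seed,
                             folds = plan$folds),
                 seed = config$seed),
            class = "adhera_cv_report")
}

#' Flat metric table of a CV report
#' @param report `adhera_cv_report`.
#' @return data.frame with one row per model x fold plus mean/sd rows.
#' @export
cv_metric_table <- function(report) {
  df <- report$folds[c("model", "fold", METRIC_NAMES)]
  df$fold <- as.character(df$fold)
  extra <- do.call(rbind, lapply(names(report$summary), function(m) {
    s <- report$summary[[m]]
    rbind(data.frame(model = m, fold = "mean", t(s$mean)),
          data.frame(model = m, fold = "sd", t(s$sd)))
  }))
  rbind(df, extra)
}

#' @export
#' @method print adhera_cv_report
print.adhera_cv_report <- function(x, ...) {
  cat(sprintf("<adhera_cv_report: %s task, %d folds, majority rate %.1f%%>\n",
              x$task, x$plan$k, x$majority_rate))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf("  %-24s acc %5.1f+/-%4.1f  prec %5.1f  rec %5.1f  spec %5.1f\n",
                m, s$mean["accuracy"], s$sd["accuracy"], s$mean["precision"],
                s$mean["recall"], s$mean["specificity"]))
  }
  invisible(x)
}
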