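## Classical baselines on the flattened (lag-unrolled + static) feature
## matrix: random forest, SVM, gradient-boosted trees, logistic regression.

#' Flatten a sample set to a plain feature matrix
#'
#' Unrolls the dynamic tensor lag-by-lag (oldest lag first) into columns
#' named `lag{i}_{channel}` — `lag1` meaning one step back — and appends
#' the static block, giving the expanded feature set shared by the fusion
#' model and every baseline.
#'
#' @param samples `adhera_samples`.
#' @return list with `x` (matrix), `y` (targets), `subject`, and `layout`
#'   (needed by [unflatten_matrix()]).
#' @export
flatten_samples <- function(samples) {
  d <- dim(samples$dynamic)
  L <- d[2L]; ch <- dimnames(samples$dynamic)[[3L]]
  cols <- list()
  for (j in seq_len(L)) {
    lag_back <- L + 1L - j
    m <- matrix(samples$dynamic[, j, ], nrow = d[1L])
    colnames(m) <- paste0("lag", lag_back, "_", ch)
    cols[[j]] <- m
  }
  x <- do.call(cbind, cols)
  if (!is.null(samples$static) && ncol(samples$static) > 0L) {
    x <- cbind(x, as.matrix(samples$static))
  }
  list(x = x, y = samples$target, subject = samples$subject,
       layout = list(lag = L, channels = ch,
                     static = colnames(samples$static)))
}

#' Rebuild a sample set from a flattened matrix
#'
#' Inverse of [flatten_samples()]; used to re-inflate SMOTE-resampled rows
#' into tensor form for the recurrent branch.
#'
#' @param x flattened feature matrix.
#' @param y targets.
#' @param layout the `layout` element returned by [flatten_samples()].
#' @param subject optional subject ids (synthetic rows inherit "synthetic").
#' @return `adhera_samples`.
#' @export
unflatten_matrix <- function(x, y, layout, subject = NULL) {
  L <- layout$lag; ch <- layout$channels
  n <- nrow(x)
  dyn <- array(NA_real_, c(n, L, length(ch)),
               dimnames = list(NULL, NULL, ch))
  for (j in seq_len(L)) {
    lag_back <- L + 1L - j
    dyn[, j, ] <- x[, paste0("lag", lag_back, "_", ch), drop = FALSE]
  }
  st <- NULL
  if (!is.null(layout$static)) {
    st <- x[, layout$static, drop = FALSE]
  }
  if (is.null(subject)) subject <- rep("resampled", n)
  new_sample_set(dyn, st, y, subject,
                 data.frame(subject_id = subject, stringsAsFactors = FALSE),
                 "flattened")
}

BASELINE_KINDS <- c("random_forest", "svm", "gradient_boosted_trees",
                    "logistic_regression")

#' Build a classical baseline model
#'
#' All baselines consume the same flattened feature set as the fusion
#' model (fair-comparison contract).
#'
#' @param kind one of `random_forest`, `svm`, `gradient_boosted_trees`,
#'   `logistic_regression`.
#' @param hyper named list of hyperparameters for the backing fit.
#' @param seed fitting seed.
#' @return untrained `adhera_model` handle.
#' @export
build_baseline <- function(kind, hyper = list(), seed = 1L) {
  kind <- match.arg(kind, BASELINE_KINDS)
  structure(list(kind = kind, hyper = hyper, seed = as.integer(seed),
                 fit = NULL, manifest = NULL, history = NULL),
            class = "adhera_model")
}

train_baseline_on <- function(model, samples) {
  flat <- if (inherits(samples, "adhera_samples")) flatten_samples(samples)
          else samples
  x <- flat$x; y <- flat$y
  stopifnot(is.matrix(x), length(y) == nrow(x))
  h <- model$hyper
  model$fit <- with_seed(model$seed, switch(
    model$kind,
    random_forest = randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)),
      ntree = h$ntree %||% 300L,
      mtry = h$mtry %||% max(1L, floor(sqrt(ncol(x))))),
    svm = e1071::svm(
      x = x, y = factor(y, levels = c(0, 1)), kernel = "radial",
      cost = h$cost %||% 1, gamma = h$gamma %||% (1 / ncol(x)),
      probability = TRUE),
    gradient_boosted_trees = {
      dtr <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = h$max_depth %||% 3L,
                      eta = h$eta %||% 0.1, nthread = 1L,
                      seed = model$seed),
        data = dtr, nrounds = h$nrounds %||% 100L, verbose = 0L)
    },
    logistic_regression = {
      df <- data.frame(y = y, x, check.names = FALSE)
      suppressWarnings(stats::glm(y ~ ., data = df,
                                  family = stats::binomial()))
    }))
  model$manifest <- list(features = colnames(x))
  model
}

predict_baseline <- function(model, samples) {
  flat <- if (inherits(samples, "adhera_samples")) flatten_samples(samples)
          else samples
  x <- flat$x
  if (!identical(colnames(x), model$manifest$features)) {
    stop("feature manifest mismatch between training and input",
         call. = FALSE)
  }
  switch(model$kind,
         random_forest =
           unname(stats::predict(model$fit, x, type = "prob")[, "1"]),
         svm = {
           pr <- stats::predict(model$fit, x, probability = TRUE)
           unname(attr(pr, "probabilities")[, "1"])
         },
         gradient_boosted_trees =
           unname(stats::predict(model$fit, xgboost::xgb.DMatrix(x))),
         logistic_regression = {
           df <- data.frame(x, check.names = FALSE)
           unname(stats::predict(model$fit, newdata = df,
                                 type = "response"))
         })
}
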