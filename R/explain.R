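## Gradient-based additive feature attributions for the fusion model
## (expected-gradients style: input gradients evaluated at random
## interpolations between each sample and background references, weighted
## by the sample-reference difference).

#' Explain a trained fusion model
#'
#' Computes per-sample additive attributions for every input feature of
#' both branches. For a sample x, a background reference b and an
#' interpolation point b + alpha (x - b) with alpha uniform on (0, 1), the
#' contribution of feature i is `(x_i - b_i) * d f / d x_i` at the
#' interpolation point; averaging over references integrates the gradient
#' along the path, so contributions sum (approximately) to
#' `f(x) - E[f(background)]`. The report gives, per named feature, the
#' mean signed attribution (direction of association with adherence) and
#' the mean absolute attribution (importance), with lag-specific names
#' like "t-1 is_adherent".
#'
#' @param model trained `adhera_model` of kind "fusion".
#' @param samples preprocessed `adhera_samples` to explain (typically the
#'   training fold).
#' @param background number of background references drawn from `samples`.
#' @param max_explained cap on the number of explained samples (drawn with
#'   the seed when `samples` is larger).
#' @param seed sampling seed.
#' @param top_k rows in the top listing.
#' @return `adhera_importance`: `table` (feature, mean_attr,
#'   mean_abs_attr, rank) and `top` (the `top_k` highest-ranked rows).
#' @export
explain <- function(model, samples, background = 25L, max_explained = 500L,
                    seed = 1L, top_k = 20L) {
  if (!inherits(model, "adhera_model") || model$kind != "fusion") {
    stop("explain() expects a trained fusion model", call. = FALSE)
  }
  inp <- fusion_inputs(model, samples)
  n <- dim(inp$X)[1L]
  if (background > n) {
    stop("background size (", background, ") exceeds available samples (",
         n, ")", call. = FALSE)
  }
  with_seed(seed, {
    bg_ix <- sample.int(n, background)
    ex_ix <- if (n > max_explained) sample.int(n, max_explained)
             else seq_len(n)
    K <- background
    Tn <- dim(inp$X)[2L]; C <- dim(inp$X)[3L]
    S_width <- if (is.null(inp$S)) 0L else ncol(inp$S)
    attr_dyn <- array(0, c(length(ex_ix), Tn, C))
    attr_st <- if (S_width > 0L) matrix(0, length(ex_ix), S_width)
    chunk <- max(1L, 2048L %/% K)
    Xbg <- inp$X[bg_ix, , , drop = FALSE]
    Sbg <- if (S_width > 0L) inp$S[bg_ix, , drop = FALSE]
    for (start in seq(1L, length(ex_ix), by = chunk)) {
      ix <- ex_ix[start:min(start + chunk - 1L, length(ex_ix))]
      m <- length(ix)
      rep_s <- rep(seq_len(m), each = K)    # sample-major ordering
      rep_b <- rep(seq_len(K), times = m)
      Xs <- inp$X[ix, , , drop = FALSE][rep_s, , , drop = FALSE]
      Xb <- Xbg[rep_b, , , drop = FALSE]
      alpha <- stats::runif(m * K)
      Xi <- Xb + alpha * (Xs - Xb)
      Si <- NULL; Ss <- NULL; Sb <- NULL
      if (S_width > 0L) {
        Ss <- inp$S[ix, , drop = FALSE][rep_s, , drop = FALSE]
        Sb <- Sbg[rep_b, , drop = FALSE]
        Si <- Sb + alpha * (Ss - Sb)
      }
      gr <- fusion_input_gradients(model, Xi, Si)
      contrib <- gr$dX * (Xs - Xb)
      for (j in seq_len(m)) {
        rows <- ((j - 1L) * K + 1L):(j * K)
        attr_dyn[start + j - 1L, , ] <-
          apply(contrib[rows, , , drop = FALSE], c(2L, 3L), mean)
      }
      if (S_width > 0L) {
        contrib_s <- gr$dS * (Ss - Sb)
        for (j in seq_len(m)) {
          rows <- ((j - 1L) * K + 1L):(j * K)
          attr_st[start + j - 1L, ] <-
            colMeans(contrib_s[rows, , drop = FALSE])
        }
      }
    }
    feats <- character(); mean_attr <- numeric(); mean_abs <- numeric()
    ch <- dimnames(inp$X)[[3L]]
    for (j in seq_len(Tn)) {
      lag_back <- Tn + 1L - j
      for (cc in seq_len(C)) {
        feats <- c(feats, sprintf("t-%d %s", lag_back, ch[cc]))
        mean_attr <- c(mean_attr, mean(attr_dyn[, j, cc]))
        mean_abs <- c(mean_abs, mean(abs(attr_dyn[, j, cc])))
      }
    }
    if (S_width > 0L) {
      feats <- c(feats, colnames(inp$S))
      mean_attr <- c(mean_attr, colMeans(attr_st))
      mean_abs <- c(mean_abs, colMeans(abs(attr_st)))
    }
    tab <- data.frame(feature = feats, mean_attr = mean_attr,
                      mean_abs_attr = mean_abs, stringsAsFactors = FALSE)
    tab$rank <- rank(-tab$mean_abs_attr, ties.method = "first")
    tab <- tab[order(tab$rank), , drop = FALSE]
    rownames(tab) <- NULL
    structure(list(table = tab,
                   top = utils::head(tab, top_k),
                   background = background,
                   n_explained = length(ex_ix)),
              class = "adhera_importance")
  })
}

#' @export
#' @method print adhera_importance
print.adhera_importance <- function(x, ...) {
  cat(sprintf("<adhera_importance: %d features, %d samples explained>\n",
              nrow(x$table), x$n_explained))
  print(utils::head(x$top, 10L), row.names = FALSE)
  invisible(x)
}

#' Fold-averaged attributions for the fusion model
#'
#' Refits the fusion model inside each subject-level cross-validation
#' fold (preprocessing and SMOTE fitted on that fold's training subjects
#' only), attributes the fold's training samples with [explain()], and
#' averages the per-fold attribution tables. Single-fit attribution ranks
#' are noisy at cohort scale; averaging over folds stabilizes them, and
#' is the package's default reporting mode for importance tables.
#'
#' @param samples `adhera_samples` with static block attached.
#' @param config `adhera_config`; `config$fusion` supplies the model
#'   hyperparameters and `config$cv_folds` the fold count.
#' @param background background references per fold.
#' @param max_explained per-fold cap on explained samples.
#' @param top_k rows in the top listing.
#' @return `adhera_importance` with fold-averaged `mean_attr` and
#'   `mean_abs_attr`.
#' @export
explain_cv <- function(samples, config = default_config(),
                       background = 40L, max_explained = 400L,
                       top_k = 20L) {
  plan <- plan_folds(samples$subject, config$cv_folds,
                     derive_seed(config$seed, "folds"))
  tabs <- vector("list", length(plan$folds))
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    tr <- subset_sample_rows(samples, samples$subject %in% fold$train)
    assert_disjoint_subjects(tr$subject, fold$test, "attribution fit")
    pp <- preprocess_fold(tr)
    sm <- smote_fold(pp$train, derive_seed(config$seed, paste0("esm", fi)))
    args <- config$fusion[intersect(names(config$fusion),
                                    names(formals(fusion_config)))]
    args$seed <- derive_seed(config$seed, paste0("efit", fi))
    fcfg <- do.call(fusion_config, args)
    m <- build_fusion(fcfg, dim(pp$train$dynamic)[2L],
                      dim(pp$train$dynamic)[3L],
                      if (is.null(pp$train$static)) 0L
                      else ncol(pp$train$static),
                      channels = pp$train$channels,
                      static_names = colnames(pp$train$static))
    m <- train_model(m, sm$samples)
    imp <- explain(m, pp$train,
                   background = min(background,
                                    length(pp$train$target)),
                   max_explained = max_explained,
                   seed = derive_seed(config$seed, paste0("eexp", fi)))
    tabs[[fi]] <- imp$table
  }
  all_t <- do.call(rbind, tabs)
  agg <- stats::aggregate(cbind(mean_attr, mean_abs_attr) ~ feature,
                          data = all_t, FUN = mean)
  agg <- agg[order(-agg$mean_abs_attr), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  structure(list(table = agg, top = utils::head(agg, top_k),
                 background = background, n_explained = NA_integer_,
                 folds = length(plan$folds)),
            class = "adhera_importance")
}
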