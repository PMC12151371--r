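test_that("fusion parameter count matches the closed-form sum", {
  cfg <- fusion_config(lstm_units = 16, static_units = 8, fusion_units = 8,
                       seed = 1)
  m <- build_fusion(cfg, n_lags = 7, n_dyn_channels = 6, n_static = 20)
  H <- 16; Hs <- 8; Hf <- 8; C <- 6; S <- 20
  expected <- 4 * H * (C + H + 1) + (S + 1) * Hs + (H + Hs + 1) * Hf +
    (Hf + 1)
  expect_equal(n_parameters(m), expected)

  # dynamic-only ablation drops the static branch entirely
  m0 <- build_fusion(cfg, 7, 6, 0)
  expect_equal(n_parameters(m0), 4 * H * (C + H + 1) + (H + 1) * Hf +
                 (Hf + 1))
  expect_error(build_fusion(cfg, 7, 0, 0), "at least one input")
})

test_that("weight initialization and predictions are seed-deterministic", {
  cfg <- fusion_config(seed = 99)
  a <- build_fusion(cfg, 4, 3, 5)
  b <- build_fusion(cfg, 4, 3, 5)
  expect_identical(a$par, b$par)
  c2 <- build_fusion(fusion_config(seed = 100), 4, 3, 5)
  expect_false(identical(a$par, c2$par))
})

test_that("LSTM gradients match central finite differences", {
  ns <- asNamespace("adhera")
  ff <- get("fusion_forward", ns); fb <- get("fusion_backward", ns)
  set.seed(3)
  n <- 4; Tl <- 3; C <- 3; S <- 2
  X <- array(stats::rnorm(n * Tl * C), c(n, Tl, C))
  Smat <- matrix(stats::rnorm(n * S), n, S)
  y <- c(1, 0, 1, 0)
  m <- build_fusion(fusion_config(lstm_units = 5, static_units = 3,
                                  fusion_units = 4, dropout = 0, seed = 11),
                    Tl, C, S)
  par <- m$par
  loss_fn <- function(p) {
    pr <- pmin(pmax(ff(p, X, Smat)$p, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  cache <- ff(par, X, Smat)
  bk <- fb(par, cache, (cache$p - y) / n, want_inputs = TRUE)
  eps <- 1e-6
  for (nm in names(par)) {
    idx <- seq_along(par[[nm]])
    if (length(idx) > 12L) idx <- sample(idx, 12L)
    for (i in idx) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(bk$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
  # input gradients of the output probability
  gin <- get("fusion_input_gradients", ns)(m, X, Smat)
  k <- 2L
  Xp <- X; Xp[k, 2, 1] <- Xp[k, 2, 1] + eps
  Xm <- X; Xm[k, 2, 1] <- Xm[k, 2, 1] - eps
  num <- (ff(par, Xp, Smat)$p[k] - ff(par, Xm, Smat)$p[k]) / (2 * eps)
  expect_equal(gin$dX[k, 2, 1], num, tolerance = 1e-6)
  Sp <- Smat; Sp[k, 1] <- Sp[k, 1] + eps
  Sm <- Smat; Sm[k, 1] <- Sm[k, 1] - eps
  num_s <- (ff(par, X, Sp)$p[k] - ff(par, X, Sm)$p[k]) / (2 * eps)
  expect_equal(gin$dS[k, 1], num_s, tolerance = 1e-6)
})

make_toy_samples <- function(n = 200, seed = 1) {
  # linearly separable: target = lag-1 adherence channel
  set.seed(seed)
  dyn <- array(0, c(n, 3, 2), dimnames = list(NULL, NULL, c("sig", "noise")))
  y <- stats::rbinom(n, 1, 0.5)
  dyn[, 3, "sig"] <- y
  dyn[, , "noise"] <- stats::rnorm(n * 3)
  st <- matrix(stats::rnorm(n), n, 1, dimnames = list(NULL, "junk"))
  structure(list(dynamic = dyn, static = st, target = y,
                 subject = sprintf("S%d", rep(1:10, length.out = n)),
                 id = data.frame(subject_id = rep("S", n)),
                 channels = c("sig", "noise"), lag = 3L, task = "daily"),
            class = "adhera_samples")
}

test_that("training fits separable data, stops early, and is reproducible", {
  samp <- make_toy_samples(200)
  cfg <- fusion_config(lstm_units = 8, static_units = 4, fusion_units = 4,
                       dropout = 0, max_epochs = 200, patience = 50,
                       validation_fraction = 0, learning_rate = 0.02,
                       seed = 7)
  m <- build_fusion(cfg, 3, 2, 1, channels = samp$channels,
                    static_names = "junk")
  fit <- train_model(m, samp)
  acc <- mean((predict_proba(fit, samp) >= 0.5) == samp$target)
  expect_equal(acc, 1.0)
  # repeated prediction identical (dropout off at predict time)
  expect_identical(predict_proba(fit, samp), predict_proba(fit, samp))
  # same seed, same data -> same fit
  fit2 <- train_model(build_fusion(cfg, 3, 2, 1, channels = samp$channels,
                                   static_names = "junk"), samp)
  expect_identical(fit$par, fit2$par)

  # max_epochs = 1 trains exactly one epoch
  cfg1 <- fusion_config(max_epochs = 1, seed = 7, validation_fraction = 0)
  h <- train_model(build_fusion(cfg1, 3, 2, 1), samp)$history
  expect_equal(nrow(h), 1L)
})

test_that("probabilities are valid and manifests are enforced", {
  samp <- make_toy_samples(80)
  cfg <- fusion_config(max_epochs = 3, seed = 2, validation_fraction = 0)
  fit <- train_model(build_fusion(cfg, 3, 2, 1, channels = samp$channels,
                                  static_names = "junk"), samp)
  p <- predict_proba(fit, samp)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated rows give identical probabilities
  dup <- samp
  dup$dynamic <- samp$dynamic[c(1, 1), , , drop = FALSE]
  dup$static <- samp$static[c(1, 1), , drop = FALSE]
  dup$target <- samp$target[c(1, 1)]
  pd <- predict_proba(fit, dup)
  expect_equal(pd[1], pd[2])
  # manifest mismatch rejected
  bad <- samp
  dimnames(bad$dynamic)[[3]] <- c("sig", "other")
  bad$channels <- c("sig", "other")
  expect_error(predict_proba(fit, bad), "manifest")
})

test_that("untrained net with zero weights outputs exactly 0.5", {
  cfg <- fusion_config(lstm_units = 4, static_units = 2, fusion_units = 3,
                       seed = 5)
  m <- build_fusion(cfg, 2, 2, 2)
  m$par <- lapply(m$par, function(p) p * 0)
  samp <- list(dynamic = array(0, c(3, 2, 2)), static = matrix(0, 3, 2),
               target = c(0, 1, 0))
  expect_equal(predict_proba(m, samp), rep(0.5, 3))
})

test_that("baselines train on the flattened feature set and are deterministic", {
  samp <- make_toy_samples(150, seed = 3)
  flat <- flatten_samples(samp)
  # 3 lags x 2 channels + 1 static = 7 columns
  expect_equal(ncol(flat$x), 7L)
  for (kind in c("random_forest", "svm", "gradient_boosted_trees",
                 "logistic_regression")) {
    fit <- train_model(build_baseline(kind, seed = 11), flat)
    p <- predict_proba(fit, flat)
    expect_true(all(p >= 0 & p <= 1))
    acc <- mean((p >= 0.5) == flat$y)
    expect_gt(acc, 0.95)  # separable toy set
  }
  f1 <- train_model(build_baseline("random_forest", seed = 11), flat)
  f2 <- train_model(build_baseline("random_forest", seed = 11), flat)
  expect_identical(predict_proba(f1, flat), predict_proba(f2, flat))
  expect_error(build_baseline("mystery"), "arg")
})

test_that("flatten and unflatten are exact inverses", {
  cohort <- tiny_cohort(n_subjects = 5, n_days = 90, seed = 44)
  samp <- build_task_samples(cohort$labels, cohort$cohort$survey, "weekly",
                             cohort$config, cohort$starts)
  pp <- asNamespace("adhera")$preprocess_fold(samp)
  flat <- flatten_samples(pp$train)
  back <- unflatten_matrix(flat$x, flat$y, flat$layout)
  expect_equal(back$dynamic, pp$train$dynamic, ignore_attr = TRUE)
  expect_equal(unname(back$static), unname(pp$train$static))
  expect_equal(back$target, pp$train$target)
})
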