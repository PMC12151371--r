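## Dual-branch fusion classifier, written from first principles in base R:
## an LSTM over the lagged dynamic tensor, a single dense (feedforward)
## layer over the static vector, concatenation of the two hidden states,
## dropout, a dense hidden layer, and a sigmoid output trained with binary
## cross-entropy and Adam. The same backward pass that trains the network
## also yields input gradients for attribution analysis.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Fusion model hyperparameters
#'
#' @param lstm_units hidden units of the recurrent (dynamic) branch.
#' @param static_units hidden units of the feedforward (static) branch.
#' @param fusion_units units of the post-concatenation hidden layer.
#' @param dropout dropout rate applied to the concatenated hidden state
#'   during training only.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_epochs training epoch cap.
#' @param patience early stopping: halt after this many consecutive epochs
#'   without validation-loss improvement, restoring the best weights.
#' @param validation_fraction fraction of training samples held out for
#'   early stopping.
#' @param seed weight-initialization / shuffling seed.
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(lstm_units = 16L, static_units = 8L,
                          fusion_units = 8L, dropout = 0.2,
                          learning_rate = 0.01, batch_size = 64L,
                          max_epochs = 40L, patience = 5L,
                          validation_fraction = 0.15, seed = 1L) {
  cfg <- list(lstm_units = as.integer(lstm_units),
              static_units = as.integer(static_units),
              fusion_units = as.integer(fusion_units),
              dropout = dropout, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              validation_fraction = validation_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$lstm_units >= 1L, cfg$fusion_units >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1, cfg$patience >= 1L,
            cfg$learning_rate > 0, cfg$max_epochs >= 1L,
            cfg$validation_fraction >= 0, cfg$validation_fraction < 1)
  class(cfg) <- c("fusion_config", "list")
  cfg
}

init_fusion_weights <- function(cfg, n_lags, n_chan, n_static) {
  H <- cfg$lstm_units; Hs <- cfg$static_units; Hf <- cfg$fusion_units
  with_seed(cfg$seed, {
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias init
    par <- list(Wx = glorot(n_chan, 4 * H), Wh = glorot(H, 4 * H), b = b)
    if (n_static > 0L) {
      par$Ws <- glorot(n_static, Hs)
      par$bs <- rep(0, Hs)
      zdim <- H + Hs
    } else zdim <- H
    par$Wf <- glorot(zdim, Hf)
    par$bf <- rep(0, Hf)
    par$Wo <- glorot(Hf, 1L)
    par$bo <- 0
    par
  })
}

#' Build a fusion model
#'
#' Architecture: dynamic input (`n_lags` time steps x `n_dyn_channels`
#' channels, oldest to newest) -> LSTM -> last hidden state; static input
#' -> dense ReLU layer; the two hidden states are concatenated, passed
#' through dropout, a dense ReLU hidden layer, and a single sigmoid output
#' optimizing binary cross-entropy. With `n_static = 0` the static branch
#' is skipped (dynamic-only ablation).
#'
#' @param config `fusion_config`.
#' @param n_lags,n_dyn_channels dynamic tensor dimensions.
#' @param n_static static feature count (0 allowed).
#' @param channels,static_names optional feature-name manifests; predictions
#'   reject inputs whose manifest differs from training.
#' @return an `adhera_model` handle (kind "fusion").
#' @export
build_fusion <- function(config, n_lags, n_dyn_channels, n_static,
                         channels = NULL, static_names = NULL) {
  if (n_dyn_channels == 0L && n_static == 0L) {
    stop("model needs at least one input branch", call. = FALSE)
  }
  par <- init_fusion_weights(config, n_lags, n_dyn_channels, n_static)
  structure(list(kind = "fusion", config = config, par = par,
                 n_lags = as.integer(n_lags),
                 n_chan = as.integer(n_dyn_channels),
                 n_static = as.integer(n_static),
                 manifest = list(channels = channels,
                                 static = static_names),
                 history = NULL),
            class = "adhera_model")
}

#' @export
#' @method print adhera_model
print.adhera_model <- function(x, ...) {
  cat(sprintf("<adhera_model kind=%s%s>\n", x$kind,
              if (x$kind == "fusion")
                sprintf(" (%d lags x %d channels + %d static)",
                        x$n_lags, x$n_chan, x$n_static) else ""))
  invisible(x)
}

#' Parameter count of a fusion topology
#'
#' Closed form: `4H(C + H + 1)` for the LSTM, `(S + 1)Hs` for the static
#' branch (0 when `S = 0`), `(H + Hs + 1)Hf` for the post-fusion layer and
#' `Hf + 1` for the output.
#'
#' @param model `adhera_model` of kind "fusion".
#' @return integer number of trainable parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$par, length, integer(1L)))
}

fusion_forward <- function(par, X, S, dropout = 0, mask = NULL) {
  n <- dim(X)[1L]; T <- dim(X)[2L]
  H <- nrow(par$Wh)
  h <- matrix(0, n, H); cst <- matrix(0, n, H)
  cache <- list(T = T, X = X, S = S, steps = vector("list", T))
  for (t in seq_len(T)) {
    Xt <- matrix(X[, t, ], nrow = n)
    A <- Xt %*% par$Wx + h %*% par$Wh +
      matrix(par$b, n, 4L * H, byrow = TRUE)
    i <- sigmoid(A[, 1:H, drop = FALSE])
    f <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_new <- o * tc
    cache$steps[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev,
                             tc = tc, h_prev = h, Xt = Xt)
    h <- h_new
  }
  if (!is.null(par$Ws)) {
    v <- S %*% par$Ws + matrix(par$bs, n, length(par$bs), byrow = TRUE)
    hs <- relu(v)
    z <- cbind(h, hs)
    cache$v <- v; cache$hs <- hs
  } else {
    z <- h
  }
  if (dropout > 0) {
    if (is.null(mask)) {
      mask <- matrix(stats::runif(length(z)) >= dropout, nrow(z), ncol(z))
    }
    zd <- z * mask / (1 - dropout)
  } else {
    mask <- NULL
    zd <- z
  }
  u <- zd %*% par$Wf + matrix(par$bf, n, length(par$bf), byrow = TRUE)
  hh <- relu(u)
  logit <- drop(hh %*% par$Wo) + par$bo
  cache$h_T <- h; cache$z <- z; cache$zd <- zd; cache$mask <- mask
  cache$dropout <- dropout; cache$u <- u; cache$hh <- hh
  cache$p <- sigmoid(logit)
  cache
}

# dlogit: per-sample upstream gradient w.r.t. the output logit.
fusion_backward <- function(par, cache, dlogit, want_inputs = FALSE) {
  n <- length(dlogit); H <- nrow(par$Wh)
  g <- list()
  dlog <- matrix(dlogit, ncol = 1L)
  g$Wo <- t(cache$hh) %*% dlog
  g$bo <- sum(dlog)
  dhh <- dlog %*% t(par$Wo)
  du <- dhh * (cache$u > 0)
  g$Wf <- t(cache$zd) %*% du
  g$bf <- colSums(du)
  dzd <- du %*% t(par$Wf)
  dz <- if (!is.null(cache$mask)) dzd * cache$mask / (1 - cache$dropout)
        else dzd
  dh <- dz[, 1:H, drop = FALSE]
  dS <- NULL
  if (!is.null(par$Ws)) {
    dhs <- dz[, (H + 1):ncol(dz), drop = FALSE]
    dv <- dhs * (cache$v > 0)
    g$Ws <- t(cache$S) %*% dv
    g$bs <- colSums(dv)
    if (want_inputs) dS <- dv %*% t(par$Ws)
  }
  g$Wx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  g$Wh <- matrix(0, H, 4L * H)
  g$b <- rep(0, 4L * H)
  dc <- matrix(0, n, H)
  dX <- if (want_inputs) array(0, dim(cache$X)) else NULL
  for (t in rev(seq_len(cache$T))) {
    st <- cache$steps[[t]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dA <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    g$Wx <- g$Wx + t(st$Xt) %*% dA
    g$Wh <- g$Wh + t(st$h_prev) %*% dA
    g$b <- g$b + colSums(dA)
    if (want_inputs) dX[, t, ] <- dA %*% t(par$Wx)
    dh <- dA %*% t(par$Wh)
    dc <- dc * st$f
  }
  list(grads = g, dX = dX, dS = dS)
}

adam_step <- function(par, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a model on a sample set
#'
#' For the fusion model: mini-batch Adam on binary cross-entropy, with
#' inverted dropout (training only) and early stopping — training halts
#' once the validation objective has failed to improve for `patience`
#' consecutive epochs, and the best-epoch weights are restored. Baselines
#' are delegated to their backing fits (see [build_baseline()]).
#'
#' @param model `adhera_model` from [build_fusion()] or [build_baseline()].
#' @param samples `adhera_samples` (fusion) or a list with `x` (matrix) and
#'   `y` (0/1 vector) for baselines; [flatten_samples()] produces the
#'   latter.
#' @return the trained `adhera_model` with `history` populated.
#' @export
train_model <- function(model, samples) {
  if (model$kind == "fusion") train_fusion_on(model, samples)
  else train_baseline_on(model, samples)
}

check_manifest <- function(model, channels, static_names) {
  m <- model$manifest
  if (!is.null(m$channels) && !is.null(channels) &&
      !identical(m$channels, channels)) {
    stop("dynamic channel manifest mismatch between training and input",
         call. = FALSE)
  }
  if (!is.null(m$static) && !is.null(static_names) &&
      !identical(m$static, static_names)) {
    stop("static feature manifest mismatch between training and input",
         call. = FALSE)
  }
  invisible(TRUE)
}

fusion_inputs <- function(model, samples) {
  X <- samples$dynamic
  stopifnot(length(dim(X)) == 3L)
  if (dim(X)[2L] != model$n_lags || dim(X)[3L] != model$n_chan) {
    stop("dynamic input dims (", dim(X)[2L], " x ", dim(X)[3L],
         ") do not match model (", model$n_lags, " x ", model$n_chan, ")",
         call. = FALSE)
  }
  S <- NULL
  if (model$n_static > 0L) {
    S <- samples$static
    if (is.null(S) || ncol(S) != model$n_static) {
      stop("static input missing or wrong width", call. = FALSE)
    }
    S <- as.matrix(S)
  }
  check_manifest(model, dimnames(X)[[3L]],
                 if (!is.null(S)) colnames(S) else NULL)
  list(X = X, S = S)
}

train_fusion_on <- function(model, samples) {
  cfg <- model$config
  inp <- fusion_inputs(model, samples)
  y <- samples$target
  n <- length(y)
  with_seed(derive_seed(cfg$seed, "train"), {
    n_val <- floor(cfg$validation_fraction * n)
    idx <- sample.int(n)
    val_ix <- if (n_val >= 5L) idx[seq_len(n_val)] else integer()
    tr_ix <- setdiff(idx, val_ix)
    Xtr <- inp$X[tr_ix, , , drop = FALSE]
    Str <- if (!is.null(inp$S)) inp$S[tr_ix, , drop = FALSE] else NULL
    ytr <- y[tr_ix]
    Xv <- inp$X[val_ix, , , drop = FALSE]
    Sv <- if (!is.null(inp$S)) inp$S[val_ix, , drop = FALSE] else NULL
    yv <- y[val_ix]
    par <- model$par
    state <- list(t = 0L,
                  m = lapply(par, function(p) p * 0),
                  v = lapply(par, function(p) p * 0))
    best <- list(loss = Inf, par = par, epoch = 0L)
    bad <- 0L
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample.int(length(ytr))
      for (start in seq(1L, length(ytr), by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, length(ytr))]
        cache <- fusion_forward(par, Xtr[bi, , , drop = FALSE],
                                if (!is.null(Str)) Str[bi, , drop = FALSE],
                                dropout = cfg$dropout)
        if (anyNA(cache$p)) {
          stop("NaN in forward pass at epoch ", ep,
               "; try a smaller learning rate", call. = FALSE)
        }
        dlogit <- (cache$p - ytr[bi]) / length(bi)
        bk <- fusion_backward(par, cache, dlogit)
        upd <- adam_step(par, bk$grads, state, cfg$learning_rate)
        par <- upd$par; state <- upd$state
      }
      trl <- bce_loss(fusion_forward(par, Xtr, Str)$p, ytr)
      if (is.na(trl)) stop("NaN training loss at epoch ", ep, call. = FALSE)
      vl <- if (length(val_ix) > 0L) bce_loss(fusion_forward(par, Xv, Sv)$p, yv)
            else trl
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = trl,
                                     val_loss = vl))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, par = par, epoch = ep)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) break
      }
    }
    model$par <- best$par
    model$history <- hist
    model$best_epoch <- best$epoch
    model$manifest <- list(channels = dimnames(inp$X)[[3L]],
                           static = if (!is.null(inp$S)) colnames(inp$S))
    model
  })
}

#' Predict adherence probabilities
#'
#' Dropout is inactive at prediction time, so repeated calls on the same
#' input are identical. The positive class (adherent) is predicted when
#' p >= 0.5.
#'
#' @param model trained `adhera_model`.
#' @param samples `adhera_samples` (fusion) or list/matrix of flattened
#'   features (baselines).
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, samples) {
  if (model$kind == "fusion") {
    inp <- fusion_inputs(model, samples)
    fusion_forward(model$par, inp$X, inp$S)$p
  } else {
    predict_baseline(model, samples)
  }
}

# Gradients of the predicted probability w.r.t. both input blocks.
fusion_input_gradients <- function(model, X, S) {
  cache <- fusion_forward(model$par, X, S)
  dlogit <- cache$p * (1 - cache$p)  # d p / d logit, per sample
  bk <- fusion_backward(model$par, cache, dlogit, want_inputs = TRUE)
  list(dX = bk$dX, dS = bk$dS, p = cache$p)
}
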