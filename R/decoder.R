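#' Configuration of the compact orientation decoder
#'
#' The decoder is a light convolutional network for single-trial ROI
#' activity: a temporal convolution (`n_temporal_kernels` kernels of length
#' `temporal_kernel_len`, same padding, no bias) learns per-ROI filters;
#' batch normalization; a depthwise spatial convolution (one kernel spanning
#' all ROIs, `spatial_depth_multiplier` kernels per temporal filter, no
#' bias) learns ROI combinations; batch normalization, ReLU, average pooling
#' over time by `pool_factor`, dropout, and a dense layer with `n_outputs`
#' units feeding a softmax. With the defaults (4 temporal kernels of length
#' 33, depth multiplier 2, pool factor 2, 68 ROIs, 100 samples) the model
#' has exactly 1502 trainable parameters.
#'
#' @param n_temporal_kernels Number of temporal convolution kernels.
#' @param temporal_kernel_len Temporal kernel length in samples (odd).
#' @param spatial_depth_multiplier Spatial kernels per temporal filter.
#' @param pool_factor Average-pooling factor over time; must divide
#'   `n_samples`.
#' @param dropout_p Dropout probability before the dense layer.
#' @param n_rois,n_samples Input dimensions (ROIs x time samples).
#' @param n_outputs Number of classes.
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(n_temporal_kernels = 4L,
                           temporal_kernel_len = 33L,
                           spatial_depth_multiplier = 2L,
                           pool_factor = 2L,
                           dropout_p = 0.25,
                           n_rois = 68L,
                           n_samples = 100L,
                           n_outputs = 2L) {
  if (n_samples %% pool_factor != 0)
    stop("`pool_factor` must divide `n_samples`", call. = FALSE)
  if (temporal_kernel_len %% 2L == 0L)
    stop("`temporal_kernel_len` must be odd (symmetric same padding)",
         call. = FALSE)
  structure(list(
    n_temporal_kernels = as.integer(n_temporal_kernels),
    temporal_kernel_len = as.integer(temporal_kernel_len),
    spatial_depth_multiplier = as.integer(spatial_depth_multiplier),
    pool_factor = as.integer(pool_factor),
    dropout_p = dropout_p,
    n_rois = as.integer(n_rois),
    n_samples = as.integer(n_samples),
    n_outputs = as.integer(n_outputs)
  ), class = "decoder_config")
}

#' Build a decoder with reproducible initialization
#'
#' Convolution and dense weights are drawn uniformly on
#' `(-1/sqrt(fan_in), 1/sqrt(fan_in))`; batch-norm scales start at 1,
#' shifts at 0; running statistics at mean 0, variance 1.
#'
#' @param config A [decoder_config()].
#' @param seed Integer seed for the parameter draw.
#' @return A `decoder_model`: list with `config`, `params`, `running`,
#'   `meta`.
#' @export
build_decoder <- function(config = decoder_config(), seed = 0L) {
  stopifnot(inherits(config, "decoder_config"))
  K <- config$n_temporal_kernels
  L <- config$temporal_kernel_len
  M8 <- K * config$spatial_depth_multiplier
  R <- config$n_rois
  Fdim <- M8 * config$n_samples / config$pool_factor
  params <- with_seed(seed, list(
    Wt = matrix(stats::runif(K * L, -1, 1) / sqrt(L), K, L),
    g1 = rep(1, K), b1 = rep(0, K),
    Ws = matrix(stats::runif(M8 * R, -1, 1) / sqrt(R), M8, R),
    g2 = rep(1, M8), b2 = rep(0, M8),
    Wd = matrix(stats::runif(config$n_outputs * Fdim, -1, 1) / sqrt(Fdim),
                config$n_outputs, Fdim),
    bd = rep(0, config$n_outputs)
  ))
  structure(list(
    config = config,
    params = params,
    running = list(mu1 = rep(0, K), var1 = rep(1, K),
                   mu2 = rep(0, M8), var2 = rep(1, M8)),
    meta = list(seed = as.integer(seed), trained = FALSE,
                epochs_run = 0L, fold = NA_integer_)
  ), class = "decoder_model")
}

#' Count the learnable scalars of a decoder
#'
#' Convolution weights, batch-norm scales and shifts, and dense weights and
#' biases; running statistics are not learnable and are not counted.
#'
#' @param model A `decoder_model`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "decoder_model"))
  sum(vapply(model$params, length, integer(1)))
}

bn_eps <- 1e-5

# ---- internal forward/backward -------------------------------------------
# Layout: input batch as array [R, T, B]; channel maps as arrays [M8, T, B].
# The per-channel affine of the first batch norm is folded through the
# spatial convolution, so the full 4 x 68 x T temporal-filter field is never
# materialized; its batch statistics come in closed form from the lag
# moments of the (fixed) input batch.

kmap_of <- function(config) rep(seq_len(config$n_temporal_kernels),
                                each = config$spatial_depth_multiplier)

# Lag moments of a padded batch: mB[j] and CB[j, j'] are the mean over
# (roi, valid t, trial) of xpad(t + j - 1) and of the product of two lagged
# copies -- exactly the mean and second moment of the temporal-conv output
# under kernel weights w, via mu = w'mB, E[u^2] = w'CB w.
conv1_lag_stats <- function(Xpad, T, L) {
  R <- dim(Xpad)[1]; Tp <- dim(Xpad)[2]; B <- dim(Xpad)[3]
  n <- R * T * B
  s0 <- rowSums(matrix(aperm(Xpad, c(2, 1, 3)), Tp))   # sum over (r, b) per tau
  cs0 <- cumsum(s0)
  mB <- (cs0[seq_len(L) + T - 1L] - c(0, cs0)[seq_len(L)]) / n
  CB <- matrix(0, L, L)
  for (d in 0:(L - 1L)) {
    w <- Tp - d
    q <- Xpad[, seq_len(w), , drop = FALSE] *
      Xpad[, d + seq_len(w), , drop = FALSE]
    qs <- rowSums(matrix(aperm(q, c(2, 1, 3)), w))
    csq <- cumsum(qs)
    v <- (csq[pmin(seq_len(L - d) + T - 1L, w)] -
            c(0, csq)[seq_len(L - d)]) / n
    for (j in seq_len(L - d)) {
      CB[j, j + d] <- v[j]
      CB[j + d, j] <- v[j]
    }
  }
  list(mB = mB, CB = CB)
}

pad_batch <- function(Xarr, L) {
  R <- dim(Xarr)[1]; T <- dim(Xarr)[2]; B <- dim(Xarr)[3]
  P <- (L - 1L) %/% 2L
  Xpad <- array(0, c(R, T + L - 1L, B))
  Xpad[, P + seq_len(T), ] <- Xarr
  Xpad
}

# Temporal convolution of channel signals: one kernel row per channel.
conv_time <- function(Spad, W_per_chan, T) {
  L <- ncol(W_per_chan)
  U <- array(0, dim = c(dim(Spad)[1], T, dim(Spad)[3]))
  for (j in seq_len(L))
    U <- U + W_per_chan[, j] * Spad[, j + 0:(T - 1L), , drop = FALSE]
  U
}

# Full (padded) correlation used in the backward pass: scatter G back over
# the padded axis weighted by the kernel.
conv_time_scatter <- function(G, W_per_chan, Tp) {
  L <- ncol(W_per_chan)
  T <- dim(G)[2]
  H <- array(0, dim = c(dim(G)[1], Tp, dim(G)[3]))
  for (j in seq_len(L))
    H[, j + 0:(T - 1L), ] <- H[, j + 0:(T - 1L), , drop = FALSE] +
      W_per_chan[, j] * G
  H
}

softmax_cols <- function(O) {
  E <- exp(sweep(O, 2L, apply(O, 2L, max)))
  sweep(E, 2L, colSums(E), "/")
}

# Forward pass. `batch` is a prepared list (see prepare_batch); in training
# mode BN statistics are the closed-form batch moments, in eval mode the
# stored running statistics. Returns output scores plus the cache needed by
# the backward pass.
decoder_fwd <- function(params, running, config, batch, training,
                        drop_mask = NULL) {
  K <- config$n_temporal_kernels
  T <- config$n_samples
  pf <- config$pool_factor
  M8 <- K * config$spatial_depth_multiplier
  km <- kmap_of(config)
  B <- batch$B
  S8 <- params$Ws %*% batch$Xr
  S <- array(S8, c(M8, T, B))
  Spad <- pad_batch(S, config$temporal_kernel_len)
  if (training) {
    mu1 <- as.vector(params$Wt %*% batch$mB)
    e2 <- rowSums((params$Wt %*% batch$CB) * params$Wt)
    var1 <- pmax(e2 - mu1^2, 0)
  } else {
    mu1 <- running$mu1
    var1 <- running$var1
  }
  sd1 <- sqrt(var1 + bn_eps)
  a1 <- params$g1 / sd1
  c1 <- params$b1 - params$g1 * mu1 / sd1
  wm <- params$Wt[km, , drop = FALSE]
  U <- conv_time(Spad, wm, T)
  Vs <- rowSums(params$Ws)
  Z <- a1[km] * U + (c1[km] * Vs)
  Zm <- matrix(Z, M8)
  if (training) {
    mu2 <- rowMeans(Zm)
    var2 <- pmax(rowMeans(Zm^2) - mu2^2, 0)
  } else {
    mu2 <- running$mu2
    var2 <- running$var2
  }
  sd2 <- sqrt(var2 + bn_eps)
  Zh <- (Z - mu2) / sd2
  Pact <- params$g2 * Zh + params$b2
  A <- Pact * (Pact > 0)
  Tq <- T %/% pf
  Q <- array(0, c(M8, Tq, B))
  for (p in seq_len(pf))
    Q <- Q + A[, seq(p, T, by = pf), , drop = FALSE]
  Q <- Q / pf
  Qf <- matrix(Q, M8 * Tq, B)
  if (training && is.null(drop_mask) && config$dropout_p > 0) {
    keep <- 1 - config$dropout_p
    drop_mask <- matrix(stats::rbinom(length(Qf), 1L, keep) / keep,
                        nrow(Qf), B)
  }
  Qd <- if (training && !is.null(drop_mask)) Qf * drop_mask else Qf
  O <- params$Wd %*% Qd + params$bd
  probs <- softmax_cols(O)
  list(O = O, probs = probs,
       cache = list(Spad = Spad, U = U, Z = Z, Zh = Zh, Pact = Pact,
                    Qd = Qd, drop_mask = drop_mask, mu1 = mu1, var1 = var1,
                    sd1 = sd1, a1 = a1, c1 = c1, mu2 = mu2, sd2 = sd2,
                    Vs = Vs, B = B))
}

decoder_bwd <- function(params, config, batch, fwd) {
  K <- config$n_temporal_kernels
  L <- config$temporal_kernel_len
  T <- config$n_samples
  pf <- config$pool_factor
  M8 <- K * config$spatial_depth_multiplier
  km <- kmap_of(config)
  ch <- fwd$cache
  B <- ch$B
  n2 <- T * B
  dO <- (fwd$probs - batch$Y) / B
  dWd <- dO %*% t(ch$Qd)
  dbd <- rowSums(dO)
  dQd <- crossprod(params$Wd, dO)
  dQf <- if (!is.null(ch$drop_mask)) dQd * ch$drop_mask else dQd
  Tq <- T %/% pf
  dQ <- array(dQf, c(M8, Tq, B))
  dA <- array(0, c(M8, T, B))
  for (p in seq_len(pf)) dA[, seq(p, T, by = pf), ] <- dQ / pf
  dP <- dA * (ch$Pact > 0)
  dPm <- matrix(dP, M8)
  Zhm <- matrix(ch$Zh, M8)
  dg2 <- rowSums(dPm * Zhm)
  db2 <- rowSums(dPm)
  dZh <- dP * params$g2
  dZhm <- matrix(dZh, M8)
  mean_dZh <- rowMeans(dZhm)
  mean_dZhZh <- rowMeans(dZhm * Zhm)
  G <- (dZh - mean_dZh - ch$Zh * mean_dZhZh) / ch$sd2
  Gm <- matrix(G, M8)
  sumG <- rowSums(Gm)
  Dm <- rowSums(Gm * matrix(ch$U, M8))
  wm <- params$Wt[km, , drop = FALSE]
  Tp <- T + L - 1L
  H <- conv_time_scatter(G, wm, Tp)
  HX <- matrix(H, M8) %*% t(matrix(batch$Xpad, config$n_rois))
  dWs <- ch$a1[km] * HX + matrix(ch$c1[km] * sumG, M8, config$n_rois)
  A33 <- matrix(0, L, M8)
  for (j in seq_len(L))
    A33[j, ] <- rowSums(matrix(G * ch$Spad[, j + 0:(T - 1L), , drop = FALSE],
                               M8))
  dWt <- matrix(0, K, L)
  dg1 <- numeric(K)
  db1 <- numeric(K)
  VsG <- ch$Vs * sumG
  for (k in seq_len(K)) {
    mk <- which(km == k)
    Ak <- if (length(mk) > 1L) rowSums(A33[, mk, drop = FALSE]) else A33[, mk]
    Dk <- sum(Dm[mk])
    Gk <- sum(VsG[mk])
    Cw <- as.vector(batch$CB %*% params$Wt[k, ])
    dinv <- -(Cw - ch$mu1[k] * batch$mB) / ch$sd1[k]^3
    dWt[k, ] <- ch$a1[k] * Ak + params$g1[k] * Dk * dinv -
      params$g1[k] * Gk * (batch$mB / ch$sd1[k] + ch$mu1[k] * dinv)
    dg1[k] <- Dk / ch$sd1[k] - ch$mu1[k] / ch$sd1[k] * Gk
    db1[k] <- Gk
  }
  list(Wt = dWt, g1 = dg1, b1 = db1, Ws = dWs, g2 = dg2, b2 = db2,
       Wd = dWd, bd = dbd)
}

# Prepare the fixed per-batch quantities reused across epochs.
prepare_batch <- function(Xarr, y01, config) {
  R <- dim(Xarr)[1]; T <- dim(Xarr)[2]; B <- dim(Xarr)[3]
  Xpad <- pad_batch(Xarr, config$temporal_kernel_len)
  st <- conv1_lag_stats_cpp(as.numeric(Xarr), R, T,
                            config$temporal_kernel_len)
  Y <- matrix(0, config$n_outputs, B)
  Y[cbind(y01 + 1L, seq_len(B))] <- 1
  list(Xr = matrix(Xarr, R), Xpad = Xpad, mB = st$mB, CB = st$CB, Y = Y,
       B = B, y01 = y01, x_num = as.numeric(Xarr))
}

# Cross-entropy of a forward result against 0/1 labels.
ce_loss <- function(probs, y01) {
  p <- probs[cbind(y01 + 1L, seq_along(y01))]
  -mean(log(pmax(p, 1e-12)))
}

# Coerce dataset-like input to [R, T, B] array + integer labels.
as_decoder_batch <- function(data) {
  if (inherits(data, "stimulus_dataset")) {
    X <- data$X; y <- data$y
  } else {
    X <- data$X; y <- data$y
  }
  y01 <- if (is.numeric(y)) as.integer(y) else as.integer(y == "inverted")
  list(Xarr = aperm(X, c(2, 3, 1)), y01 = y01)
}

#' Class scores and probabilities of a decoder on trials
#'
#' Runs the network in evaluation mode (running batch-norm statistics,
#' dropout inactive).
#'
#' @param model A `decoder_model`.
#' @param X A 3-D array (trials x ROIs x time), a single ROI x time matrix,
#'   or a `stimulus_dataset`.
#' @return List with `scores` (trials x classes), `probs` (rows sum to 1)
#'   and `labels` (predicted, `"upright"`/`"inverted"`).
#' @export
predict_decoder <- function(model, X) {
  stopifnot(inherits(model, "decoder_model"))
  if (inherits(X, "stimulus_dataset")) X <- X$X
  if (is.matrix(X)) X <- array(X, c(1L, nrow(X), ncol(X)))
  if (dim(X)[2] != model$config$n_rois || dim(X)[3] != model$config$n_samples)
    stop("input shape does not match the model configuration", call. = FALSE)
  Xarr <- aperm(X, c(2, 3, 1))
  fwd <- cnn_eval_forward(model$params, unclass(model$config),
                          as.numeric(Xarr), model$running)
  list(scores = t(fwd$O), probs = t(fwd$probs),
       labels = c("upright", "inverted")[apply(fwd$probs, 2L, which.max)])
}

#' Optimizer and schedule settings for decoder training
#'
#' Adaptive-moment gradient descent on the cross-entropy, with
#' early stopping on the validation loss.
#'
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Epochs without validation-loss improvement before
#'   stopping; the best-validation parameters are restored.
#' @return A `decoder_hyper` list.
#' @export
decoder_hyper <- function(lr = 1e-3, batch_size = 64L, max_epochs = 150L,
                          patience = 10L) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "decoder_hyper")
}

#' Train a decoder on standardized trials
#'
#' Minimizes the cross-entropy with Adam; the mini-batch partition is drawn
#' once per run (batch order reshuffled every epoch), batch-norm running
#' statistics are updated with momentum 0.1, and training stops early when
#' the validation loss has not improved for `patience` epochs. The returned
#' model carries the parameters of the best validation epoch. Deterministic
#' given data, `seed` and `hyper`.
#'
#' @param model A built `decoder_model` (its current parameters are the
#'   initialization).
#' @param train,val Standardized datasets (`stimulus_dataset` or lists with
#'   `X` trials x ROIs x time and `y`); `val` must be non-empty.
#' @param seed Integer seed for batching and dropout.
#' @param hyper A [decoder_hyper()].
#' @return The trained `decoder_model` with updated `meta` (`epochs_run`,
#'   `best_epoch`, `val_loss`).
#' @export
train_decoder <- function(model, train, val, seed = 0L,
                          hyper = decoder_hyper()) {
  stopifnot(inherits(model, "decoder_model"))
  config <- model$config
  tr <- as_decoder_batch(train)
  vl <- as_decoder_batch(val)
  if (!length(vl$y01)) stop("empty validation set", call. = FALSE)
  n <- length(tr$y01)
  params <- model$params
  running <- model$running
  momentum <- 0.1
  cfgl <- unclass(config)
  Fdim <- (config$n_temporal_kernels * config$spatial_depth_multiplier) *
    config$n_samples / config$pool_factor
  val_x <- as.numeric(vl$Xarr)
  with_seed(seed, {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = hyper$batch_size)
    batches <- lapply(starts, function(s) {
      sel <- idx[s:min(s + hyper$batch_size - 1L, n)]
      prepare_batch(tr$Xarr[, , sel, drop = FALSE], tr$y01[sel], config)
    })
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0), t = 0L)
    best <- list(loss = Inf, params = params, running = running, epoch = 0L)
    stall <- 0L
    epoch <- 0L
    while (epoch < hyper$max_epochs) {
      epoch <- epoch + 1L
      for (b in sample(seq_along(batches))) {
        batch <- batches[[b]]
        drop_mask <- if (config$dropout_p > 0) {
          keep <- 1 - config$dropout_p
          matrix(stats::rbinom(Fdim * batch$B, 1L, keep) / keep, Fdim,
                 batch$B)
        } else NULL
        step <- cnn_train_step(params, cfgl, batch$x_num, batch$mB,
                               batch$CB, batch$Y, batch$y01, drop_mask)
        nb <- batch$B * config$n_rois * config$n_samples
        n2 <- batch$B * config$n_samples
        running$mu1 <- (1 - momentum) * running$mu1 + momentum * step$mu1
        running$var1 <- (1 - momentum) * running$var1 +
          momentum * step$var1 * nb / max(nb - 1, 1)
        running$mu2 <- (1 - momentum) * running$mu2 + momentum * step$mu2
        running$var2 <- (1 - momentum) * running$var2 +
          momentum * step$var2 * n2 / max(n2 - 1, 1)
        grads <- step$grads
        state$t <- state$t + 1L
        for (nm in names(params)) {
          g <- grads[[nm]]
          state$m[[nm]] <- 0.9 * state$m[[nm]] + 0.1 * g
          state$v[[nm]] <- 0.999 * state$v[[nm]] + 0.001 * g^2
          mhat <- state$m[[nm]] / (1 - 0.9^state$t)
          vhat <- state$v[[nm]] / (1 - 0.999^state$t)
          params[[nm]] <- params[[nm]] - hyper$lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      vfwd <- cnn_eval_forward(params, cfgl, val_x, running)
      vloss <- ce_loss(vfwd$probs, vl$y01)
      if (vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, params = params, running = running,
                     epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= hyper$patience) break
      }
    }
    model$params <- best$params
    model$running <- best$running
    model$meta$trained <- TRUE
    model$meta$epochs_run <- epoch
    model$meta$best_epoch <- best$epoch
    model$meta$val_loss <- best$loss
    model$meta$train_seed <- as.integer(seed)
    model
  })
}

#' Confusion matrix and accuracy on a test set
#'
#' @param model A trained `decoder_model`.
#' @param test Standardized test dataset.
#' @return List with `confusion` (2 x 2, rows = true, cols = predicted,
#'   upright first) and `accuracy`.
#' @export
evaluate_decoder <- function(model, test) {
  te <- as_decoder_batch(test)
  if (!length(te$y01)) stop("empty test set", call. = FALSE)
  pr <- predict_decoder(model, aperm(te$Xarr, c(3, 1, 2)))
  pred <- as.integer(pr$labels == "inverted")
  lev <- c("upright", "inverted")
  confusion <- table(factor(lev[te$y01 + 1L], levels = lev),
                     factor(lev[pred + 1L], levels = lev))
  confusion <- matrix(as.integer(confusion), 2L, 2L,
                      dimnames = list(true = lev, predicted = lev))
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / sum(confusion))
}
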