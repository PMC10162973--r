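#' Settings for layer-wise relevance propagation
#'
#' @param epsilon Positive stabilizer added (sign-matched) to every layer's
#'   pre-activation denominator.
#' @param target_class Class whose pre-softmax score is decomposed
#'   (2 = inverted, the default).
#' @return An `lrp_config` list.
#' @export
lrp_config <- function(epsilon = 1e-6, target_class = 2L) {
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  structure(list(epsilon = epsilon, target_class = as.integer(target_class)),
            class = "lrp_config")
}

# ---- generic layer stack --------------------------------------------------
# A stack is a list of layers:
#   dense:      W (out x in), b
#   conv_time:  W (K x L), b (K); input R x T matrix -> [K, R, T]
#   conv_space: W (M x R), b (M), kmap (M); input [K, R, T] -> [M, T]
#   relu, flatten, pool_time (factor)
# Batch norms never appear: they are folded into the adjacent convolution's
# effective weights and biases before propagation.

stab <- function(z, eps) z + eps * ifelse(z >= 0, 1, -1)

lrp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- x
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    a <- acts[[i]]
    acts[[i + 1L]] <- switch(ly$type,
      dense = as.vector(ly$W %*% a + ly$b),
      relu = a * (a > 0),
      flatten = as.vector(a),
      pool_time = {
        pf <- ly$factor
        Tq <- ncol(a) %/% pf
        out <- matrix(0, nrow(a), Tq)
        for (p in seq_len(pf)) out <- out + a[, seq(p, ncol(a), by = pf),
                                              drop = FALSE]
        out / pf
      },
      conv_time = {
        L <- ncol(ly$W); T <- ncol(a); P <- (L - 1L) %/% 2L
        xpad <- cbind(matrix(0, nrow(a), P), a, matrix(0, nrow(a), L - 1L - P))
        out <- array(0, c(nrow(ly$W), nrow(a), T))
        for (k in seq_len(nrow(ly$W))) {
          acc <- matrix(ly$b[k], nrow(a), T)
          for (j in seq_len(L))
            acc <- acc + ly$W[k, j] * xpad[, j + 0:(T - 1L), drop = FALSE]
          out[k, , ] <- acc
        }
        out
      },
      conv_space = {
        T <- dim(a)[3]
        out <- matrix(0, nrow(ly$W), T)
        for (m in seq_len(nrow(ly$W)))
          out[m, ] <- ly$W[m, ] %*% a[ly$kmap[m], , ] + ly$b[m]
        out
      },
      stop("unknown layer type: ", ly$type)
    )
  }
  acts
}

lrp_backward <- function(layers, acts, relevance, eps) {
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    a <- acts[[i]]
    z <- acts[[i + 1L]]
    relevance <- switch(ly$type,
      dense = {
        ratio <- relevance / stab(z - ly$b, eps)
        as.vector(crossprod(ly$W, ratio)) * a
      },
      relu = relevance,
      flatten = array(relevance, dim = dim(a)),
      pool_time = {
        pf <- ly$factor
        out <- matrix(0, nrow(a), ncol(a))
        for (p in seq_len(pf)) out[, seq(p, ncol(a), by = pf)] <-
          relevance / pf
        out
      },
      conv_space = {
        ratio <- relevance / stab(z - ly$b, eps) # M x T
        out <- array(0, dim = dim(a))            # K x R x T
        for (m in seq_len(nrow(ly$W))) {
          k <- ly$kmap[m]
          out[k, , ] <- out[k, , ] +
            a[k, , ] * outer(ly$W[m, ], ratio[m, ])
        }
        out
      },
      conv_time = {
        K <- nrow(ly$W); L <- ncol(ly$W)
        R <- nrow(a); T <- ncol(a); P <- (L - 1L) %/% 2L
        xpad <- cbind(matrix(0, R, P), a, matrix(0, R, L - 1L - P))
        Rpad <- matrix(0, R, T + L - 1L)
        for (k in seq_len(K)) {
          ratio <- matrix(relevance[k, , ], R, T) /
            stab(matrix(z[k, , ], R, T) - ly$b[k], eps)
          for (j in seq_len(L))
            Rpad[, j + 0:(T - 1L)] <- Rpad[, j + 0:(T - 1L)] +
              ly$W[k, j] * xpad[, j + 0:(T - 1L), drop = FALSE] * ratio
        }
        Rpad[, P + seq_len(T), drop = FALSE]
      },
      stop("unknown layer type: ", ly$type)
    )
  }
  relevance
}

#' Fold a trained decoder into an explicit layer stack
#'
#' Batch normalizations are absorbed into the adjacent convolutions using
#' the running statistics, yielding effective weights `gamma * W / sigma`
#' and biases `beta - gamma * mu / sigma`. The stack's evaluation-mode
#' forward pass is identical to the decoder's.
#'
#' @param model A trained `decoder_model`.
#' @return List of layers consumable by the relevance propagator.
#' @export
fold_decoder_layers <- function(model) {
  p <- model$params
  r <- model$running
  cfg <- model$config
  sd1 <- sqrt(r$var1 + bn_eps)
  sd2 <- sqrt(r$var2 + bn_eps)
  list(
    list(type = "conv_time", W = p$Wt * (p$g1 / sd1),
         b = p$b1 - p$g1 * r$mu1 / sd1),
    list(type = "conv_space", W = p$Ws * (p$g2 / sd2),
         b = p$b2 - p$g2 * r$mu2 / sd2, kmap = kmap_of(cfg)),
    list(type = "relu"),
    list(type = "pool_time", factor = cfg$pool_factor),
    list(type = "flatten"),
    list(type = "dense", W = p$Wd, b = p$bd)
  )
}

#' Explain one trial with epsilon-rule relevance propagation
#'
#' The pre-softmax class score of the target class (by default the inverted
#' class) is decomposed backward through the folded network with the
#' epsilon-rule: at every linear layer, relevance flows to the inputs in
#' proportion to their contribution `z_jk` to the unit's stabilized
#' contribution sum `z_k = sum_j z_jk` (biases shape the forward pass and
#' the ReLU gating but do not absorb relevance, so the decomposition is
#' conservative up to the stabilizer); average pooling redistributes
#' relevance uniformly to the pooled samples; ReLU passes relevance through
#' unchanged. Dropout is inactive.
#'
#' @param model A trained `decoder_model`.
#' @param X One trial (ROIs x time matrix), standardized exactly as at
#'   training time.
#' @param cfg An [lrp_config()].
#' @return A `relevance_map`: list with `values` (signed ROIs x time
#'   matrix), `score` (the decomposed class score o), `target_class`.
#' @export
lrp_explain_trial <- function(model, X, cfg = lrp_config()) {
  stopifnot(inherits(model, "decoder_model"))
  if (!is.matrix(X) || nrow(X) != model$config$n_rois ||
      ncol(X) != model$config$n_samples)
    stop("trial shape does not match the model configuration", call. = FALSE)
  layers <- fold_decoder_layers(model)
  res <- lrp_stack_explain(layers, X, cfg$target_class, cfg$epsilon)
  structure(list(values = res$relevance, score = res$score,
                 target_class = cfg$target_class), class = "relevance_map")
}

# Explain an arbitrary layer stack (used directly by the tests on linear
# models).
lrp_stack_explain <- function(layers, x, target_class, epsilon) {
  acts <- lrp_forward(layers, x)
  out <- acts[[length(acts)]]
  rel_out <- rep(0, length(out))
  rel_out[target_class] <- out[target_class]
  rel <- lrp_backward(layers, acts, rel_out, epsilon)
  list(relevance = rel, score = out[target_class], output = out)
}

#' Fold-level inversion relevance map
#'
#' Explains every inverted-orientation test trial with every seed-model of
#' the fold, averages the maps across trials within each seed-model, then
#' across seed-models: one signed ROIs x time map per cross-validation
#' fold.
#'
#' @param models List of trained seed-models of one fold.
#' @param test Standardized test set of the fold (`stimulus_dataset` or
#'   list with `X`, `y`); only trials labelled `"inverted"` are explained.
#' @param cfg An [lrp_config()].
#' @return A `relevance_map` whose `values` are the fold average.
#' @export
fold_relevance_map <- function(models, test, cfg = lrp_config()) {
  X <- if (inherits(test, "stimulus_dataset") || is.list(test)) test$X else test
  y <- test$y
  inv <- if (is.null(y)) seq_len(dim(X)[1]) else which(y == "inverted")
  if (!length(inv)) stop("no inverted trials in the test set", call. = FALSE)
  seed_maps <- lapply(models, function(m) {
    maps <- lapply(inv, function(i) lrp_explain_trial(m, X[i, , ], cfg)$values)
    Reduce(`+`, maps) / length(maps)
  })
  avg <- Reduce(`+`, seed_maps) / length(seed_maps)
  structure(list(values = avg, score = NA_real_,
                 target_class = cfg$target_class, n_trials = length(inv),
                 n_models = length(models)), class = "relevance_map")
}

#' Relevance scores per ROI and fold
#'
#' For every fold map, the signed maximum relevance of each ROI within the
#' analysis window (150-200 ms post-stimulus by default, both endpoints
#' included: 11 samples at 200 Hz) is extracted.
#'
#' @param fold_maps List of `relevance_map` objects (or ROIs x time
#'   matrices), one per fold, sharing the time axis.
#' @param window Two-element numeric, analysis window in s.
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first map column, s.
#' @return Folds x ROIs matrix (columns named by [dk_rois()] when the maps
#'   have 68 rows).
#' @export
relevance_scores <- function(fold_maps, window = c(0.150, 0.200), fs = 200,
                             t0 = 0) {
  mats <- lapply(fold_maps, function(m)
    if (inherits(m, "relevance_map")) m$values else m)
  T <- ncol(mats[[1L]])
  t <- t0 + (seq_len(T) - 1L) / fs
  idx <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  if (!length(idx) || window[1] < t[1] - 1e-9 || window[2] > t[T] + 1e-9)
    stop("analysis window outside the epoch", call. = FALSE)
  RS <- t(vapply(mats, function(m)
    apply(m[, idx, drop = FALSE], 1L, max), numeric(nrow(mats[[1L]]))))
  if (ncol(RS) == 68L) colnames(RS) <- dk_rois()
  RS
}
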