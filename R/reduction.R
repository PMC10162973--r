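#' Anti-aliased resampling and half-open cropping of multichannel series
#'
#' Resamples a channels-by-time matrix from `fs_in` to `fs_out` (integer
#' ratio) with a zero-phase FIR low-pass (order 64, cutoff 0.8 of the target
#' Nyquist, applied forward-backward so there is no group delay) followed by
#' subsampling, then crops to the half-open window `[t_a, t_b)`. Sample `k`
#' (1-based) of the result sits at time `t_a + (k - 1) / fs_out`, so the
#' stimulus-onset sample (0 s) opens the post-stimulus block.
#'
#' @param x Numeric matrix, channels x time (a vector is treated as one
#'   channel).
#' @param fs_in,fs_out Input/output sampling rates, Hz; `fs_in` must be an
#'   integer multiple of `fs_out`.
#' @param window Two-element numeric, crop window `[t_a, t_b)` in seconds.
#' @param t0 Time of the first input sample, s.
#' @return Matrix channels x `(t_b - t_a) * fs_out`, with attributes `fs`
#'   and `t0`.
#' @export
resample_and_crop <- function(x, fs_in, fs_out, window, t0 = -1) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (fs_in < fs_out) stop("`fs_in` must be >= `fs_out`", call. = FALSE)
  m <- fs_in / fs_out
  if (abs(m - round(m)) > 1e-9)
    stop("`fs_in` must be an integer multiple of `fs_out`", call. = FALSE)
  m <- as.integer(round(m))
  n_in <- ncol(x)
  t_end <- t0 + n_in / fs_in
  if (window[1] < t0 - 1e-9 || window[2] > t_end + 1e-9)
    stop("crop window outside the signal time span", call. = FALSE)
  if (m > 1L) {
    b <- signal::fir1(64, 0.8 / m)
    xf <- t(apply(x, 1L, function(row) signal::filtfilt(b, row)))
    x <- xf[, seq(1L, n_in, by = m), drop = FALSE]
  }
  k0 <- round((window[1] - t0) * fs_out)          # 0-based first kept sample
  n_out <- round((window[2] - window[1]) * fs_out)
  if (k0 < 0 || k0 + n_out > ncol(x))
    stop("crop window outside the signal time span", call. = FALSE)
  out <- x[, k0 + seq_len(n_out), drop = FALSE]
  attr(out, "fs") <- fs_out
  attr(out, "t0") <- window[1]
  out
}

#' First-principal-component waveform of a vertex bundle
#'
#' Reduces the `3 * N_r` vertex signals of one ROI to a single waveform: the
#' score series of the first principal component (rows are features, time
#' samples are observations; features are mean-centered). The sign ambiguity
#' is removed by a polarity rule: let `f*` be the row with the largest
#' absolute loading on the first component, and let its contribution series
#' be `loading(f*) * f*`; if the sign of the component at its own
#' largest-magnitude sample differs from the sign of the contribution series
#' at *its* largest-magnitude sample, the component is negated. Anchoring to
#' the signed contribution (rather than the raw row) makes the output
#' invariant both to the arbitrary sign of the eigendecomposition and to a
#' global sign flip of the bundle.
#'
#' @param bundle A `vertex_bundle` (see [generate_vertex_bundle()]) or a
#'   numeric matrix of row signals.
#' @return Numeric vector, one sample per input time sample.
#' @export
roi_first_component <- function(bundle) {
  X <- if (inherits(bundle, "vertex_bundle")) bundle$signals else bundle
  if (!is.matrix(X) || nrow(X) < 1L || ncol(X) < 2L)
    stop("bundle must have >= 1 row and >= 2 time samples", call. = FALSE)
  Xc <- X - rowMeans(X)
  if (all(abs(Xc) < 1e-12))
    stop("degenerate bundle: zero variance in every row", call. = FALSE)
  sv <- svd(t(Xc), nu = 1L, nv = 1L)              # obs x features
  pc1 <- sv$u[, 1L] * sv$d[1L]                    # score series over time
  loading <- sv$v[, 1L]
  jstar <- which.max(abs(loading))
  contrib <- loading[jstar] * X[jstar, ]
  s_pc <- sign(pc1[which.max(abs(pc1))])
  s_f <- sign(contrib[which.max(abs(contrib))])
  if (s_pc != 0 && s_f != 0 && s_pc != s_f) pc1 <- -pc1
  pc1
}

#' Assemble the per-subject, per-stimulus trial collection
#'
#' Validates and packs single-trial ROI matrices with their orientation
#' labels into the dataset unit consumed by the decoder protocol.
#'
#' @param trials List of numeric matrices, all of identical dimension
#'   (ROIs x time), or a 3-D array trials x ROIs x time.
#' @param labels Character vector in `{"upright", "inverted"}`, one per trial.
#' @param subject Subject index.
#' @param stimulus Stimulus type label.
#' @param fs,t0 Sampling rate (Hz) and first-sample time (s).
#' @return A `stimulus_dataset`: list with `X` (M x R x T array), `y`,
#'   `subject`, `stimulus`, `M`, `fs`, `t0`.
#' @export
assemble_stimulus_dataset <- function(trials, labels, subject, stimulus,
                                      fs = 200, t0 = 0) {
  if (is.array(trials) && length(dim(trials)) == 3L) {
    X <- trials
  } else {
    if (!length(trials)) stop("empty trial collection", call. = FALSE)
    dims <- vapply(trials, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("inconsistent trial dimensions across the collection", call. = FALSE)
    X <- array(0, dim = c(length(trials), dims[1, 1], dims[2, 1]))
    for (i in seq_along(trials)) X[i, , ] <- trials[[i]]
  }
  M <- dim(X)[1]
  if (M == 0L) stop("empty trial collection", call. = FALSE)
  if (length(labels) != M)
    stop("`labels` length must match the number of trials", call. = FALSE)
  if (!all(labels %in% c("upright", "inverted")))
    stop("labels must be 'upright' or 'inverted'", call. = FALSE)
  structure(list(X = X, y = labels, subject = subject, stimulus = stimulus,
                 M = M, fs = fs, t0 = t0), class = "stimulus_dataset")
}

#' Reduce a cohort to decoder-ready datasets
#'
#' Applies [resample_and_crop()] to every trial of every dataset: the full
#' `[-0.5, 0.5)` s matrix (200 samples at 200 Hz) is retained for the
#' time/time-frequency signature analyses, and the post-stimulus `[0, 0.5)`
#' block (68 x 100) feeds the decoder.
#'
#' @param cohort Output of [generate_cohort()].
#' @param fs_out Target sampling rate, Hz.
#' @return List with the same stimulus/subject structure; each element has
#'   `epoch` (dataset cropped to `[-0.5, 0.5)`) and `decoder` (dataset
#'   cropped to `[0, 0.5)`).
#' @export
reduce_cohort <- function(cohort, fs_out = 200) {
  lapply(cohort, function(subjects) {
    lapply(subjects, function(ds) {
      M <- ds$M
      ep <- NULL; dec <- NULL
      for (i in seq_len(M)) {
        full <- resample_and_crop(ds$X[i, , ], ds$fs, fs_out,
                                  window = c(-0.5, 0.5), t0 = ds$t0)
        if (is.null(ep)) {
          ep <- array(0, c(M, nrow(full), ncol(full)))
          dec <- array(0, c(M, nrow(full), ncol(full) / 2L))
        }
        ep[i, , ] <- full
        dec[i, , ] <- full[, (ncol(full) / 2L + 1L):ncol(full)]
      }
      list(
        epoch = assemble_stimulus_dataset(ep, ds$y, ds$subject, ds$stimulus,
                                          fs = fs_out, t0 = -0.5),
        decoder = assemble_stimulus_dataset(dec, ds$y, ds$subject, ds$stimulus,
                                            fs = fs_out, t0 = 0)
      )
    })
  })
}

#' Standardize train/validation/test splits with training statistics
#'
#' Maps every matrix entry to `(x - mu) / sigma`, where `mu` and `sigma` are
#' the scalar mean and standard deviation over *all* entries of *all*
#' training trials (optionally per ROI). The identical transform is applied
#' to the validation and test sets, so no statistic leaks from them.
#'
#' @param train,val,test `stimulus_dataset` objects or 3-D arrays
#'   (trials x ROIs x time); `val`/`test` may be `NULL`.
#' @param per_roi When `TRUE`, use one mean/SD per ROI instead of the scalar
#'   default.
#' @return List `train`, `val`, `test` (same types as supplied) plus
#'   `scaler` (list with `mu`, `sigma`, `per_roi`) for reuse.
#' @export
standardize_split <- function(train, val = NULL, test = NULL, per_roi = FALSE) {
  get_x <- function(d) if (inherits(d, "stimulus_dataset")) d$X else d
  set_x <- function(d, X) {
    if (inherits(d, "stimulus_dataset")) { d$X <- X; d } else X
  }
  Xtr <- get_x(train)
  if (is.null(Xtr) || !length(Xtr)) stop("empty training set", call. = FALSE)
  if (per_roi) {
    mu <- apply(Xtr, 2L, mean)
    sigma <- apply(Xtr, 2L, stats::sd)
  } else {
    mu <- mean(Xtr)
    sigma <- stats::sd(as.vector(Xtr))
  }
  if (any(sigma <= 0) || any(!is.finite(sigma)))
    stop("degenerate training set: zero variance", call. = FALSE)
  scaler <- list(mu = mu, sigma = sigma, per_roi = per_roi)
  apply_one <- function(d) {
    if (is.null(d)) return(NULL)
    set_x(d, apply_scaler(get_x(d), scaler))
  }
  list(train = apply_one(train), val = apply_one(val), test = apply_one(test),
       scaler = scaler)
}

#' Apply a stored standardization to new data
#' @param X 3-D array trials x ROIs x time.
#' @param scaler Scaler component returned by [standardize_split()].
#' @return Standardized array of the same shape.
#' @export
apply_scaler <- function(X, scaler) {
  if (scaler$per_roi) {
    d <- dim(X)
    sweep(sweep(X, 2L, scaler$mu), 2L, scaler$sigma, "/")
  } else {
    (X - scaler$mu) / scaler$sigma
  }
}
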