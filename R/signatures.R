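#' Event-related potentials per condition
#'
#' Pointwise trial average of the ROI activity, separately per orientation.
#'
#' @param dataset A `stimulus_dataset` (epoch-cropped), or a 3-D array
#'   trials x ROIs x time together with `y`.
#' @param y Labels when `dataset` is a bare array.
#' @return List with `upright` and `inverted` ROIs x time matrices and the
#'   per-condition trial counts.
#' @export
compute_erp <- function(dataset, y = NULL) {
  if (inherits(dataset, "stimulus_dataset")) {
    X <- dataset$X; y <- dataset$y
  } else X <- dataset
  out <- list()
  for (cond in c("upright", "inverted")) {
    idx <- which(y == cond)
    if (!length(idx)) stop("no trials for condition '", cond, "'",
                           call. = FALSE)
    out[[cond]] <- apply(X[idx, , , drop = FALSE], c(2L, 3L), mean)
  }
  out$n <- c(upright = sum(y == "upright"), inverted = sum(y == "inverted"))
  out
}

#' Complex Morlet continuous wavelet transform
#'
#' FFT-based convolution with unit-energy complex Morlet wavelets. The
#' number of cycles defaults to `max(3, f / 2)`, trading temporal for
#' spectral resolution toward low frequencies.
#'
#' @param x Numeric vector, one signal.
#' @param fs Sampling rate, Hz.
#' @param freqs Frequency grid, Hz.
#' @param n_cycles Cycles per wavelet (recycled over `freqs`).
#' @return Complex matrix, `length(freqs)` x `length(x)`.
#' @export
morlet_cwt <- function(x, fs, freqs, n_cycles = pmax(3, freqs / 2)) {
  n <- length(x)
  n_cycles <- rep_len(n_cycles, length(freqs))
  nfft <- stats::nextn(2L * n, 2L)
  Xf <- stats::fft(c(x, rep(0, nfft - n)))
  out <- matrix(0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigma_t <- n_cycles[i] / (2 * pi * f)
    half <- min(ceiling(5 * sigma_t * fs), n - 1L)
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    Wf <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::fft(Xf * Wf, inverse = TRUE) / nfft
    out[i, ] <- conv[half + seq_len(n)]          # center the kernel
  }
  out
}

# Cone-of-influence mask: TRUE where the wavelet support (sqrt(2) sigma_t)
# fits inside the epoch.
coi_mask <- function(freqs, times, fs, n_cycles = pmax(3, freqs / 2)) {
  n_cycles <- rep_len(n_cycles, length(freqs))
  sigma_t <- n_cycles / (2 * pi * freqs)
  edge <- sqrt(2) * sigma_t
  outer(edge, times - times[1], `<=`) &
    outer(edge, times[length(times)] - times, `<=`)
}

#' Event-related (de)synchronization map of one trial
#'
#' Squares the Morlet transform coefficients to power, then normalizes each
#' frequency row by its pre-stimulus baseline: `ERD/S = (P - B) / B`, with
#' `B(f)` the mean power over the baseline interval. Computed per trial
#' (mixed evoked + induced activity) and averaged across trials afterwards.
#'
#' @param x Numeric vector, single-ROI epoch covering the baseline.
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @param freqs Frequency grid, Hz.
#' @param baseline Baseline interval `[a, b)` in s.
#' @param n_cycles Cycles per wavelet.
#' @return A `tf_map`: list with `power` (ERD/S values, freqs x time),
#'   `freqs`, `times`, `kind = "erds"`, `baseline`.
#' @export
erds_map <- function(x, fs, t0 = -0.5, freqs = 4:40,
                     baseline = c(-0.5, 0), n_cycles = pmax(3, freqs / 2)) {
  times <- t0 + (seq_along(x) - 1L) / fs
  bidx <- which(times >= baseline[1] - 1e-9 & times < baseline[2] - 1e-9)
  if (!length(bidx))
    stop("the series does not cover the baseline interval", call. = FALSE)
  P <- Mod(morlet_cwt(x, fs, freqs, n_cycles))^2
  B <- rowMeans(P[, bidx, drop = FALSE])
  if (any(B <= 0)) stop("zero baseline power at some frequency",
                        call. = FALSE)
  structure(list(power = (P - B) / B, freqs = freqs, times = times,
                 kind = "erds", baseline = baseline), class = "tf_map")
}

#' ERD/S of trial-averaged mixed power
#'
#' Computes `|CWT|^2` per trial (so induced, non-phase-locked activity
#' survives), averages the power across trials, and normalizes the average
#' by its own baseline. Normalizing the trial mean (rather than each trial)
#' avoids the upward bias of single-trial baseline ratios, whose few
#' effective baseline samples make `E[1/B]` large.
#'
#' @param trials Numeric matrix, trials x time (one ROI).
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @param freqs Frequency grid, Hz.
#' @param baseline Baseline interval `[a, b)` in s.
#' @param n_cycles Cycles per wavelet.
#' @return A `tf_map` with the baseline-normalized mean power.
#' @export
erds_average <- function(trials, fs, t0 = -0.5, freqs = 4:40,
                         baseline = c(-0.5, 0),
                         n_cycles = pmax(3, freqs / 2)) {
  if (is.vector(trials)) trials <- matrix(trials, nrow = 1)
  times <- t0 + (seq_len(ncol(trials)) - 1L) / fs
  bidx <- which(times >= baseline[1] - 1e-9 & times < baseline[2] - 1e-9)
  if (!length(bidx))
    stop("the series does not cover the baseline interval", call. = FALSE)
  P <- 0
  for (i in seq_len(nrow(trials)))
    P <- P + Mod(morlet_cwt(trials[i, ], fs, freqs, n_cycles))^2
  P <- P / nrow(trials)
  B <- rowMeans(P[, bidx, drop = FALSE])
  if (any(B <= 0)) stop("zero baseline power at some frequency",
                        call. = FALSE)
  structure(list(power = (P - B) / B, freqs = freqs, times = times,
                 kind = "erds", baseline = baseline), class = "tf_map")
}

#' Condition-wise ERD/S for one ROI
#'
#' @param dataset Epoch-cropped `stimulus_dataset`.
#' @param roi ROI label or row index.
#' @param freqs,n_cycles Wavelet grid settings.
#' @return List with `upright` and `inverted` `tf_map` objects (see
#'   [erds_average()]).
#' @export
erds_condition_average <- function(dataset, roi, freqs = 4:40,
                                   n_cycles = pmax(3, freqs / 2)) {
  ri <- if (is.character(roi)) roi_index(roi) else roi
  out <- list()
  for (cond in c("upright", "inverted")) {
    idx <- which(dataset$y == cond)
    if (!length(idx)) stop("no trials for condition '", cond, "'",
                           call. = FALSE)
    out[[cond]] <- erds_average(dataset$X[idx, ri, , drop = TRUE],
                                dataset$fs, dataset$t0, freqs,
                                n_cycles = n_cycles)
  }
  out
}

# Paired t statistics for all sign-flip permutations at once: with paired
# differences d (n x p), only the permuted mean changes; the sum of squares
# is flip-invariant.
perm_t_stats <- function(d, signs) {
  n <- nrow(d)
  s2 <- colSums(d^2)
  m <- (signs %*% d) / n
  sd2 <- (rep(1, nrow(signs)) %o% s2 - n * m^2) / (n - 1)
  sd2[sd2 < 1e-24] <- 1e-24
  m / sqrt(sd2 / n)
}

# Maximum absolute cluster mass of a t vector under 1-D adjacency.
max_cluster_mass_1d <- function(tv, thr) {
  supra <- abs(tv) > thr
  if (!any(supra)) return(0)
  pos <- which(supra)
  grp <- cumsum(c(TRUE, diff(pos) > 1))
  # runs of supra-threshold |t| can mix signs only across threshold crossings;
  # split runs by sign to keep clusters homogeneous
  sgn_grp <- paste(grp, sign(tv[pos]))
  masses <- tapply(tv[pos], sgn_grp, sum)
  max(abs(masses))
}

cluster_runs_1d <- function(tv, thr) {
  out <- list()
  for (s in c(1, -1)) {
    supra <- (s * tv) > thr
    if (!any(supra)) next
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values))
      out[[length(out) + 1L]] <- starts[i]:ends[i]
  }
  out
}

#' Cluster-based permutation test of paired time courses
#'
#' Paired t-statistics across subjects at every time point; contiguous
#' supra-threshold runs (two-tailed t critical value at the cluster-forming
#' level, df = n - 1) form clusters whose mass is the summed t; the null
#' distribution is the maximum absolute cluster mass over random
#' subject-wise sign flips of the condition differences; a cluster's p-value
#' is the proportion of null masses at least as large as its own.
#'
#' @param cond_a,cond_b Subjects x time matrices (paired rows).
#' @param n_perm Number of sign-flip permutations.
#' @param alpha Significance level for reporting clusters.
#' @param cluster_alpha Cluster-forming (pointwise) level.
#' @param seed Integer seed for the permutation draw.
#' @return A `cluster_result`: list with `t` (time course), `clusters`
#'   (index vectors), `masses`, `p`, `sig` (logical per cluster),
#'   `sig_mask` (logical per time point), `threshold`, `null` (the
#'   permutation distribution).
#' @export
cluster_test_time <- function(cond_a, cond_b, n_perm = 5000L, alpha = 0.05,
                              cluster_alpha = 0.05, seed = 0L) {
  n <- nrow(cond_a)
  if (n < 5L) stop("fewer than 5 subjects: insufficient data", call. = FALSE)
  if (!identical(dim(cond_a), dim(cond_b)))
    stop("condition matrices must have matching shape", call. = FALSE)
  d <- cond_a - cond_b
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  tobs <- as.vector(perm_t_stats(d, matrix(1, 1L, n)))
  clusters <- cluster_runs_1d(tobs, thr)
  masses <- vapply(clusters, function(ix) sum(tobs[ix]), numeric(1))
  null <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    tp <- perm_t_stats(d, signs)
    vapply(seq_len(n_perm), function(i) max_cluster_mass_1d(tp[i, ], thr),
           numeric(1))
  })
  p <- vapply(masses, function(ms) mean(null >= abs(ms)), numeric(1))
  sig <- p < alpha
  sig_mask <- rep(FALSE, ncol(d))
  for (i in which(sig)) sig_mask[clusters[[i]]] <- TRUE
  structure(list(t = tobs, clusters = clusters, masses = masses, p = p,
                 sig = sig, sig_mask = sig_mask, threshold = thr,
                 null = null, n_perm = n_perm), class = "cluster_result")
}

# Connected components of a logical matrix under 4-neighbour adjacency,
# via per-column run labelling + union-find merge of row-overlapping runs
# in adjacent columns.
label_components_4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  prev_runs <- NULL
  for (cc in seq_len(nc)) {
    col <- mask[, cc]
    if (!any(col)) { prev_runs <- NULL; next }
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    ids <- integer(nrow(runs))
    for (k in seq_len(nrow(runs))) {
      parent[length(parent) + 1L] <- length(parent) + 1L
      ids[k] <- length(parent)
      labels[runs[k, 1]:runs[k, 2], cc] <- ids[k]
      if (!is.null(prev_runs)) {
        for (q in seq_len(nrow(prev_runs))) {
          if (prev_runs[q, 1] <= runs[k, 2] && runs[k, 1] <= prev_runs[q, 2]) {
            ra <- find(ids[k]); rb <- find(prev_runs[q, 3])
            if (ra != rb) parent[ra] <- rb
          }
        }
      }
    }
    prev_runs <- cbind(runs, ids)
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), find, integer(1))
    remap <- match(roots, unique(roots))
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  labels
}

max_cluster_mass_2d <- function(tm, thr, valid) {
  best <- 0
  for (s in c(1, -1)) {
    mask <- (s * tm > thr) & valid
    if (!any(mask)) next
    lab <- label_components_4(mask)
    if (max(lab) == 0L) next
    masses <- abs(tapply(tm[lab > 0L], lab[lab > 0L], sum))
    best <- max(best, masses)
  }
  best
}

#' Cluster-based permutation test of paired time-frequency maps
#'
#' Identical machinery to [cluster_test_time()] with 4-neighbour adjacency
#' over the frequency x time grid. An optional validity mask (e.g. the
#' wavelet cone of influence) restricts the clustered points.
#'
#' @param cond_a,cond_b 3-D arrays, subjects x frequencies x time.
#' @param n_perm,alpha,cluster_alpha,seed As in [cluster_test_time()].
#' @param valid Optional logical frequencies x time matrix of points
#'   eligible for clustering.
#' @return A `cluster_result` with `t_map` (frequencies x time), `clusters`
#'   (logical masks), `masses`, `p`, `sig`, `sig_mask`, `null`.
#' @export
cluster_test_timefreq <- function(cond_a, cond_b, n_perm = 5000L,
                                  alpha = 0.05, cluster_alpha = 0.05,
                                  seed = 0L, valid = NULL) {
  n <- dim(cond_a)[1]
  if (n < 5L) stop("fewer than 5 subjects: insufficient data", call. = FALSE)
  if (!identical(dim(cond_a), dim(cond_b)))
    stop("condition arrays must have matching shape", call. = FALSE)
  nf <- dim(cond_a)[2]; nt <- dim(cond_a)[3]
  if (is.null(valid)) valid <- matrix(TRUE, nf, nt)
  d <- matrix(cond_a - cond_b, n)                 # n x (nf * nt)
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  tobs <- matrix(as.vector(perm_t_stats(d, matrix(1, 1L, n))), nf, nt)
  clusters <- list(); masses <- numeric(0)
  for (s in c(1, -1)) {
    mask <- (s * tobs > thr) & valid
    lab <- label_components_4(mask)
    if (max(lab) > 0L) {
      for (id in seq_len(max(lab))) {
        cl <- lab == id
        clusters[[length(clusters) + 1L]] <- cl
        masses <- c(masses, sum(tobs[cl]))
      }
    }
  }
  null <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    tp <- perm_t_stats(d, signs)
    vapply(seq_len(n_perm), function(i)
      max_cluster_mass_2d(matrix(tp[i, ], nf, nt), thr, valid), numeric(1))
  })
  p <- vapply(masses, function(ms) mean(null >= abs(ms)), numeric(1))
  sig <- p < alpha
  sig_mask <- matrix(FALSE, nf, nt)
  for (i in which(sig)) sig_mask <- sig_mask | clusters[[i]]
  structure(list(t_map = tobs, clusters = clusters, masses = masses, p = p,
                 sig = sig, sig_mask = sig_mask, threshold = thr,
                 null = null, n_perm = n_perm), class = "cluster_result")
}
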