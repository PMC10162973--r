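#' Condition-effect specification for the synthetic cortical generator
#'
#' Describes how upright and inverted presentations of one stimulus type
#' differ at the cortical level. The generator plants, at the designated
#' `effect_rois`, (i) an N170-like monophasic negative evoked deflection
#' (Gaussian window, `evoked_sigma` wide) whose amplitude is multiplied by
#' `evoked_amp_gain` and whose peak is delayed by `evoked_peak_delay` in the
#' inverted condition, and (ii) a random-phase theta burst whose power is
#' multiplied by `theta_power_gain` in the inverted condition. All other ROIs
#' carry only 1/f^alpha background noise.
#'
#' A control (house-like) stimulus is obtained with `evoked_amp_gain = 1`,
#' `evoked_peak_delay = 0`, `theta_power_gain = 1`: the evoked response is
#' still present but identical across orientations.
#'
#' @param effect_rois Character vector of ROI labels (subset of [dk_rois()])
#'   carrying condition differences.
#' @param evoked_peak_time Peak latency of the upright evoked deflection, s.
#' @param evoked_peak_delay Additional latency for the inverted condition, s.
#' @param evoked_amp Amplitude (a.u., applied with negative sign) of the
#'   upright evoked deflection.
#' @param evoked_amp_gain Multiplier (> 0) on the evoked amplitude for the
#'   inverted condition.
#' @param evoked_sigma Width (standard deviation) of the Gaussian evoked
#'   window, s.
#' @param theta_freq Frequency of the induced burst, Hz.
#' @param theta_burst_window Two-element vector, burst support in s (within
#'   the post-stimulus half-second).
#' @param theta_amp Burst amplitude (a.u.) in the upright condition.
#' @param theta_power_gain Multiplier (> 0) on the burst *power* for the
#'   inverted condition (amplitude is scaled by its square root).
#' @param noise_sd Standard deviation of the background noise, a.u.
#' @param spectral_exponent Exponent alpha of the 1/f^alpha background.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(effect_rois = character(0),
                        evoked_peak_time = 0.170,
                        evoked_peak_delay = 0.015,
                        evoked_amp = 2.4,
                        evoked_amp_gain = 1.5,
                        evoked_sigma = 0.025,
                        theta_freq = 5,
                        theta_burst_window = c(0.05, 0.45),
                        theta_amp = 1.2,
                        theta_power_gain = 2,
                        noise_sd = 1,
                        spectral_exponent = 1) {
  if (length(effect_rois)) roi_index(effect_rois)  # validates labels
  for (nm in c("evoked_amp_gain", "theta_power_gain"))
    if (get(nm) <= 0) stop(sprintf("`%s` must be > 0", nm), call. = FALSE)
  if (length(theta_burst_window) != 2L ||
      theta_burst_window[1] < 0 || theta_burst_window[2] > 0.5 ||
      diff(theta_burst_window) <= 0)
    stop("`theta_burst_window` must be an increasing interval within [0, 0.5]",
         call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  structure(list(
    effect_rois = effect_rois,
    evoked_peak_time = evoked_peak_time,
    evoked_peak_delay = evoked_peak_delay,
    evoked_amp = evoked_amp,
    evoked_amp_gain = evoked_amp_gain,
    evoked_sigma = evoked_sigma,
    theta_freq = theta_freq,
    theta_burst_window = theta_burst_window,
    theta_amp = theta_amp,
    theta_power_gain = theta_power_gain,
    noise_sd = noise_sd,
    spectral_exponent = spectral_exponent
  ), class = "effect_spec")
}

#' Default effect specifications for the three stimulus types
#'
#' Faces and bodies are social stimuli with inversion effects at two
#' right-hemisphere visual-stream ROIs (lateral occipital and superior
#' parietal cortex); the body effect is somewhat weaker than the face effect.
#' Houses are the non-social control: the same evoked response occurs but
#' there is no condition difference (all gains 1, no delay).
#'
#' @param effect_rois ROIs carrying the social-stimulus inversion effects.
#' @return Named list of [effect_spec()] objects (`face`, `body`, `house`).
#' @export
default_effect_specs <- function(effect_rois = c("lateraloccipital_rh",
                                                 "superiorparietal_rh")) {
  list(
    face  = effect_spec(effect_rois),
    body  = effect_spec(effect_rois, evoked_amp_gain = 1.4,
                        theta_power_gain = 1.8),
    house = effect_spec(effect_rois, evoked_amp_gain = 1,
                        evoked_peak_delay = 0, theta_power_gain = 1)
  )
}

# 1/f^alpha Gaussian noise, one row per channel, via spectral shaping of
# white noise. The shaping gains are normalized to unit mean square so the
# output standard deviation stays ~= sd.
pink_noise <- function(n_chan, n_samp, fs, alpha, sd) {
  if (sd == 0) return(matrix(0, n_chan, n_samp))
  w <- matrix(stats::rnorm(n_chan * n_samp), n_chan, n_samp)
  if (alpha == 0) return(sd * w)
  f <- (seq_len(n_samp) - 1) * fs / n_samp
  f[f > fs / 2] <- fs - f[f > fs / 2]          # two-sided symmetric axis
  g <- c(0, f[-1]^(-alpha / 2))                 # kill DC
  g <- g / sqrt(mean(g^2))
  sp <- t(stats::mvfft(t(w))) * rep(g, each = n_chan)
  sd * Re(t(stats::mvfft(t(sp), inverse = TRUE))) / n_samp
}

# Deterministic condition-dependent components of one trial (no RNG).
trial_components <- function(condition, effect, t, phases) {
  inverted <- condition == "inverted"
  amp <- effect$evoked_amp * if (inverted) effect$evoked_amp_gain else 1
  tp <- effect$evoked_peak_time + if (inverted) effect$evoked_peak_delay else 0
  evoked <- -amp * exp(-(t - tp)^2 / (2 * effect$evoked_sigma^2))
  bw <- effect$theta_burst_window
  env <- ifelse(t >= bw[1] & t <= bw[2],
                0.5 - 0.5 * cos(2 * pi * (t - bw[1]) / diff(bw)), 0)
  tamp <- effect$theta_amp * if (inverted) sqrt(effect$theta_power_gain) else 1
  theta <- outer(phases, 2 * pi * effect$theta_freq * t, function(p, w) sin(w + p))
  list(evoked = evoked, theta = tamp * (env * t(theta)))  # theta: T x n_eff
}

#' Generate one synthetic ROI-level trial
#'
#' Produces a 68 x (2 fs) matrix spanning \[-1, 1) s around stimulus onset:
#' independent 1/f^alpha noise in every ROI, plus, in the effect ROIs of
#' `effect`, the condition-dependent evoked deflection and random-phase theta
#' burst described in [effect_spec()]. The random draws (noise, burst phases)
#' depend only on `seed`, never on `condition`, so two conditions generated
#' with the same seed differ exactly by the deterministic effect components.
#'
#' @param condition `"upright"` or `"inverted"`.
#' @param effect An [effect_spec()].
#' @param seed Non-negative integer; the trial is deterministic given it.
#' @param fs Sampling rate, Hz (200 native, or 1000 to exercise resampling).
#' @return A `trial_matrix`: list with `X` (68 x 2*fs, rownames [dk_rois()]),
#'   `y`, `subject`, `stimulus`, `fs`, `t0 = -1`.
#' @export
generate_roi_trial <- function(condition, effect, seed, fs = 200) {
  condition <- match.arg(condition, c("upright", "inverted"))
  stopifnot(inherits(effect, "effect_spec"))
  n_roi <- 68L
  n_samp <- as.integer(2 * fs)
  t <- -1 + (seq_len(n_samp) - 1) / fs
  eff_idx <- roi_index(effect$effect_rois)
  X <- with_seed(seed, {
    noise <- pink_noise(n_roi, n_samp, fs, effect$spectral_exponent,
                        effect$noise_sd)
    phases <- stats::runif(length(eff_idx), 0, 2 * pi)
    cmp <- trial_components(condition, effect, t, phases)
    if (length(eff_idx)) {
      noise[eff_idx, ] <- noise[eff_idx, ] +
        rep(cmp$evoked, each = length(eff_idx)) + t(cmp$theta)
    }
    noise
  })
  rownames(X) <- dk_rois()
  new_trial_matrix(X, y = condition, fs = fs, t0 = -1)
}

new_trial_matrix <- function(X, y, subject = NA_integer_,
                             stimulus = NA_character_, fs, t0) {
  structure(list(X = X, y = y, subject = subject, stimulus = stimulus,
                 fs = fs, t0 = t0), class = "trial_matrix")
}

#' Generate a vertex-level bundle from a ROI waveform
#'
#' Emulates the `3 * N_r` free-orientation source signals of the vertices
#' belonging to one ROI: every row is the ROI waveform scaled by a fixed
#' mixing weight plus independent Gaussian noise. Test bed for the
#' first-principal-component reduction.
#'
#' @param roi_signal Numeric vector, the ground-truth ROI waveform.
#' @param n_vertices Number of cortical vertices (>= 1); the bundle has
#'   `3 * n_vertices` rows.
#' @param mixing_seed Integer seed for weights and noise.
#' @param noise_sd Noise standard deviation, a.u.
#' @param weights Optional fixed mixing weights (length `3 * n_vertices`);
#'   when `NULL` they are drawn uniformly on \[-1, 1\], re-anchored so that at
#'   least one |weight| exceeds 0.5.
#' @param roi_id ROI label carried as metadata.
#' @return A `vertex_bundle`: list with `signals` (3 n_vertices x T),
#'   `weights`, `roi_id`, `fs`, `t0`.
#' @export
generate_vertex_bundle <- function(roi_signal, n_vertices, mixing_seed,
                                   noise_sd = 0.1, weights = NULL,
                                   roi_id = NA_character_) {
  if (!is.numeric(n_vertices) || n_vertices < 1)
    stop("`n_vertices` must be >= 1", call. = FALSE)
  n_row <- 3L * as.integer(n_vertices)
  tlen <- length(roi_signal)
  with_seed(mixing_seed, {
    if (is.null(weights)) {
      weights <- stats::runif(n_row, -1, 1)
      if (max(abs(weights)) <= 0.5)
        weights[which.max(abs(weights))] <- sign(weights[which.max(abs(weights))] + .Machine$double.eps) * 0.75
    }
    stopifnot(length(weights) == n_row)
    signals <- outer(weights, roi_signal) +
      matrix(stats::rnorm(n_row * tlen, sd = noise_sd), n_row, tlen)
    structure(list(signals = signals, weights = weights, roi_id = roi_id,
                   fs = NA_real_, t0 = NA_real_), class = "vertex_bundle")
  })
}

#' Generate a synthetic multi-subject cohort
#'
#' For every subject and stimulus type, a balanced set of upright/inverted
#' trials is generated with [generate_roi_trial()], mirroring the study
#' layout of one block of pictures per stimulus type with half of the
#' pictures upright. Fully reproducible: per-trial seeds are derived from
#' `seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param trials_per_condition Trials per orientation per subject-stimulus.
#' @param effects Named list of [effect_spec()] objects, one per stimulus
#'   type; see [default_effect_specs()].
#' @param seed Base integer seed.
#' @param fs Sampling rate passed to the trial generator.
#' @return Named list (one element per stimulus type) of lists of
#'   `stimulus_dataset` objects, one per subject.
#' @export
generate_cohort <- function(n_subjects, trials_per_condition,
                            effects = default_effect_specs(), seed = 1,
                            fs = 200) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2", call. = FALSE)
  if (trials_per_condition < 1)
    stop("`trials_per_condition` must be >= 1", call. = FALSE)
  if (is.null(names(effects)) || any(!nzchar(names(effects))))
    stop("`effects` must be a named list of effect_spec objects", call. = FALSE)
  labels <- rep(c("upright", "inverted"), each = trials_per_condition)
  out <- vector("list", length(effects))
  names(out) <- names(effects)
  counter <- 0L
  for (stim in names(effects)) {
    eff <- effects[[stim]]
    if (!inherits(eff, "effect_spec"))
      stop("missing or invalid effect spec for stimulus '", stim, "'",
           call. = FALSE)
    subj_list <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      trials <- vector("list", length(labels))
      for (i in seq_along(labels)) {
        counter <- counter + 1L
        trials[[i]] <- generate_roi_trial(labels[i], eff,
                                          seed = derive_seed(seed, counter),
                                          fs = fs)$X
      }
      subj_list[[s]] <- assemble_stimulus_dataset(trials, labels,
                                                  subject = s, stimulus = stim,
                                                  fs = fs, t0 = -1)
    }
    out[[stim]] <- subj_list
  }
  out
}
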