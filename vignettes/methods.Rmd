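---
title: "Decoding stimulus inversion from cortical EEG: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus inversion from cortical EEG: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(invcnn)
```

## The scientific question

Faces and bodies are perceived *holistically*: turning them upside down
disrupts perception (the face- and body-inversion effects) in a way that
turning a house upside down does not. Electrophysiologically, inversion
modulates the N170, a negative event-related potential peaking around
170 ms after stimulus onset, which becomes larger and later for inverted
social stimuli, and is accompanied by increased low-frequency
(theta/alpha) synchronization.

`invcnn` implements a data-driven pipeline to localize these effects in
*source space*: single-trial cortical activity summarized over the 68
Desikan-Killiany regions of interest (ROIs) is decoded for stimulus
orientation (upright vs. inverted) with a compact convolutional network,
the network's decisions are explained by layer-wise relevance propagation
(LRP), the most discriminant ROIs are selected by three non-parametric
criteria, and the selected ROIs are characterized with ERPs and
event-related (de)synchronization (ERD/S) maps under cluster-based
permutation statistics.

Because the original recordings are not redistributable, the package
ships a synthetic-data module that emulates the statistical structure the
analysis assumes. Every stage is exercised against this generator with
known ground truth.

## The synthetic generator

`generate_roi_trial()` produces one trial as a 68-ROI x time matrix over
[-1, 1) s at 200 Hz (or 1000 Hz, to exercise the resampling stage):

* **Background**: independent 1/f^alpha Gaussian noise per ROI
  (`spectral_exponent` alpha = 1, `noise_sd` = 1 a.u.), produced by
  spectral shaping of white noise. The average periodogram slope over
  2-40 Hz is -alpha by construction.
* **Evoked component** (effect ROIs only): a Gaussian-windowed
  (sigma = 25 ms) *negative* deflection peaking at 170 ms, the simplest
  waveform reproducing a "larger and later" N170: in the inverted
  condition its amplitude is multiplied by `evoked_amp_gain` (1.5) and its
  peak delayed by `evoked_peak_delay` (15 ms).
* **Induced component** (effect ROIs only): a Hann-windowed theta burst
  (5 Hz, 50-450 ms) with per-trial uniform random phase, so it cancels in
  the ERP but survives in total power; inverted trials carry
  `theta_power_gain` (2) times its power.

Randomness (noise, burst phase) depends only on the seed, never on the
condition, so an upright/inverted pair generated from one seed differs
exactly by the deterministic effect components -- the ground truth that
the recovery tests rely on.

**Effect-size calibration.** No quantitative cortical effect sizes are
available for the real data, so the defaults were calibrated once against
the study-level observable that *is* reported: decoding accuracy. With
`evoked_amp = 2.4` (vs. unit noise SD) and `theta_amp = 1.2`, an
8-subject synthetic face cohort decodes at ~0.73, the order of the
reported 0.69 face accuracy, while the control (house-like) specification
-- identical evoked response in both conditions, no power gain -- decodes
at chance. These values were then frozen; they are tunable in
`effect_spec()` but are not estimates of the real cortical amplitudes.

The generator does **not** emulate: inter-ROI noise correlation and
volume-conduction leakage, trial-to-trial latency jitter of the evoked
component, alpha-band dynamics, subject-level amplitude variability, or
artifacts. Passing recovery tests therefore demonstrates correctness of
the *pipeline*, not expected performance on real recordings.

`generate_vertex_bundle()` emulates the `3 * N_r` free-orientation vertex
signals of one ROI (fixed random mixing weights times the ROI waveform,
plus sensor noise) and is the test bed for the first-principal-component
reduction.

## ROI reduction

`resample_and_crop()` lowpass-filters (order-64 FIR at 0.8 of the target
Nyquist, applied forward-backward so the group delay is exactly zero) and
subsamples to 200 Hz, then crops half-open windows: `[-0.5, 0.5)` for the
signature analyses and `[0, 0.5)` -- 100 samples, onset sample included --
for the decoder.

`roi_first_component()` reduces a vertex bundle to one waveform per trial:
the first principal component score series (features = rows,
observations = time samples, feature-mean centered). The PCA sign is fixed
by a polarity rule anchored to the *contribution series* of the row with
the largest absolute loading (loading times row): the component is negated
if its extremum polarity disagrees with the contribution's extremum
polarity. Anchoring to the signed contribution rather than the raw row is
deliberate: it makes the output invariant both to the arbitrary sign
returned by the eigendecomposition and to a global sign flip of the bundle
(vertex orientations in free-orientation source models are themselves of
arbitrary sign). PCA is computed per trial, which is what the decoder
consumes; a pooled-across-trials variant was rejected because it would mix
trial-specific noise structure into the loadings.

`standardize_split()` standardizes with a single scalar mean/SD computed
over all entries of all *training* trials (per-ROI statistics are
available behind `per_roi = TRUE`), and applies the same transform to
validation and test sets -- no statistic leaks from them.

## The decoder

`decoder_config()` fixes the architecture: a temporal convolution (4
kernels, length 33 samples = 165 ms, same padding, no bias) learns per-ROI
filters; batch normalization; a depthwise spatial convolution (one
68-weight kernel spanning all ROIs, 2 kernels per temporal filter, no
bias) learns ROI combinations; batch normalization; ReLU; average pooling
by 2 over time; dropout (p = 0.25); a dense layer with 2 units; softmax.
The parameter count is

4*33 + 2*4 + 8*68 + 2*8 + (8*50*2 + 2) = 1502.

The kernel length and pooling factor are the unique pair among plausible
values consistent with this printed count; they are a reconstruction, not
a published configuration.

**Training.** Adam (learning rate 1e-3, batch size 64), cross-entropy,
early stopping on the validation loss (patience 10, cap 150 epochs; these
cohort sizes converge in well under 60 epochs, so a longer patience only
adds runtime). A stratified 10% of the training pool is held out per fold
and seed as the validation set. The mini-batch partition is drawn once per
run and only the batch *order* is reshuffled across epochs; with fixed
batches the batch-norm statistics of the first convolution have an exact
closed form (the convolution is linear in its kernel, so the channel mean
and variance are quadratic forms in precomputed lag moments of the batch),
which both the R reference implementation and the compiled training kernel
exploit. Training is bit-deterministic given data, seed, and settings; the
gradient of every parameter -- including the path through the batch-norm
statistics -- is verified against central finite differences in the test
suite, and the compiled kernels are asserted equal to the R reference.

**Protocol.** `run_loso_protocol()` implements leave-one-subject-out
cross-validation with `n_seeds` random initializations per fold (seeds
0..n-1; a fixed list rather than sampled seeds, for reproducibility);
metrics are seed-averaged per fold. `compare_stimulus_accuracies()` runs
the three pairwise fold-level signed-rank tests with a Bonferroni factor
of 3, plus one-sided tests against the 0.5 chance level.

## Relevance propagation

`lrp_explain_trial()` decomposes the pre-softmax score of the inverted
class back to the input with the epsilon-rule. Both batch norms are first
folded into the adjacent convolution's effective weights and biases using
the running statistics (the folded stack's forward pass is asserted
identical to the decoder's). At every linear layer, relevance flows in
proportion to each input's contribution `z_jk`, stabilized by
`epsilon * sign(.)` (default 1e-6). The denominator is the *contribution
sum* `sum_j z_jk`: the folded biases shape the forward pass and the ReLU
gating but do not absorb relevance. This choice is deliberate -- with the
bias inside the denominator, units whose pre-activation is near zero let
a small bias absorb or amplify relevance essentially without bound, and
conservation failed by factors of 10-100 on trained networks; with the
contribution sum, the map total equals the class score to within ~2%.
Average pooling redistributes relevance uniformly over the pooled samples;
ReLU passes relevance through unchanged; dropout is inactive.

Per fold, maps of all inverted test trials are averaged within each
seed-model and then across seed-models (`fold_relevance_map()`), and each
ROI's *relevance score* is the signed maximum within 150-200 ms -- both
endpoints included, 11 samples at 200 Hz (`relevance_scores()`). The
signed (not absolute) maximum is used because positive relevance is
evidence *for* the inverted class. Relevance scores are stable in rank
across stabilizers 1e-8 to 1e-4; single-trial maps are less so, which is
why scores are always computed from fold-averaged maps.

## ROI selection

Three criteria are applied to the folds x 68 score table of a social
stimulus, each a family of Wilcoxon signed-rank tests with Bonferroni
correction inside its own family (68, 67, 68 tests) at alpha = 0.05:

1. scores significantly **above the per-fold average** across all ROIs
   (one-sided; the average includes the ROI under test);
2. **not significantly different from the maximally relevant ROI**
   (two-sided; the maximum ROI itself is kept);
3. significantly **different from the control stimulus** (houses;
   two-sided).

The selection is the intersection. The signed-rank test discards zero
differences and averages tied ranks; for up to 25 non-zero pairs the exact
null distribution is computed by convolution over the (possibly tied)
ranks, which equals exhaustive sign enumeration; beyond that, the normal
approximation with continuity correction is used. A Pratt variant of zero
handling is available behind `zero_method = "pratt"`.

**Fold count matters.** With `F` folds the smallest attainable exact
p-value is `2^-F` (one-sided). At the full 23-fold protocol this is
1.2e-7, far below the corrected threshold 0.05/68; at 8 folds it is
3.9e-3, *above* it, so criteria 1 and 3 cannot flag any ROI and the
selection is empty regardless of the data. Desk-scale selection therefore
needs 12 or more subjects (2^-12 = 2.4e-4 < 7.4e-4), and the recovery
tests use 12-subject cohorts where selection is the quantity under test.

## Signatures

`compute_erp()` is the pointwise trial mean per condition.
`morlet_cwt()` convolves with unit-energy complex Morlet wavelets on a
4-40 Hz grid with `n_cycles = max(3, f/2)` -- a balance of temporal and
spectral resolution at theta; the exact parameterization is a package
choice, not a published value. Squared magnitudes give *mixed* (evoked +
induced) power, computed per trial so induced activity survives
averaging.

ERD/S normalization: per frequency, the baseline is the mean power over
[-0.5, 0) s and the map is `(P - B)/B`. `erds_map()` normalizes a single
trial by its own baseline (its baseline mean is zero by construction);
`erds_average()` and `erds_condition_average()` normalize the
*trial-averaged* power instead, because a single trial's baseline has only
~3 effective degrees of freedom per frequency under these wavelets and the
expectation of `1/B` then inflates every per-trial ratio by a large,
purely statistical offset (~+0.7 for stationary noise). Normalizing the
trial mean removes that bias without affecting the evoked/induced mix.

`cluster_test_time()` and `cluster_test_timefreq()` are paired
cluster-based permutation tests: pointwise paired t statistics across
subjects; cluster-forming threshold at the two-tailed t critical value for
p = 0.05 with df = n-1 (a standard default; the original threshold is not
published); clusters are sign-homogeneous contiguous runs (1-D) or
4-neighbour components (2-D); the null distribution is the maximum
absolute cluster mass over random subject-wise sign flips (5000 by
default, fixed seed recorded); a cluster's p-value is the fraction of null
masses at least as large. Points inside the wavelet cone of influence
(within sqrt(2) sigma_t of an epoch edge) can be excluded via the `valid`
mask, and the time-frequency test is run on post-stimulus samples only.
Type-I error is verified to sit in [0.03, 0.07] under null simulations.

## Problem sizes used by the tests

The test suite runs everything at desk scale, chosen so the full suite
completes on one CPU while leaving every contract measurable: module
fixtures use 8-subject cohorts with 12 trials per condition and 2 seeds;
the recovery experiment uses ten 8-subject cohorts with 16 trials per
condition and 3 seeds (the conditions stated for it); calibration uses
1000 null datasets at 200 permutations and 1000 null score tables; the
signature checks use one 12-subject cohort with 5000-permutation cluster
tests. The full-scale protocol (23 subjects x 10 seeds x 3 stimuli = 690
trainings) is enumerated by `run_pipeline(dry_run = TRUE)` and runs with
the same code path.

## Known limitations

* The generator's realism limits what green tests mean for real data (see
  above); in particular, decoding accuracy on synthetic cohorts is a
  calibration target, not a prediction.
* The epsilon-rule is implemented throughout, including the input layer;
  box-constrained input-layer rules are not provided.
* Resampling supports integer rate ratios only (the pipeline needs
  1000 -> 200 Hz).
* Selection at fewer than 12 folds is structurally empty under exact
  Bonferroni-corrected signed-rank tests (see "Fold count matters").
* Cohort containers are exchanged as R objects / RDS plus CSV reports; no
  HDF5 interface is provided.
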