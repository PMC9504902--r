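---
title: "Decoding motor imagery from EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

smrdecode implements three two-class motor-imagery (MI) decoders over a
common epoch container, together with the synthetic sensorimotor-rhythm
generator used to exercise them. This vignette explains the science behind
each component, the tunable parameters and their defaults, the numerical
choices, and what the simulation-based tests do and do not establish.

## The signal being decoded

Hand motor imagery desynchronizes mu (8–12 Hz) and beta (14–30 Hz)
oscillations over the contralateral sensorimotor cortex: imagining the left
hand suppresses rhythm power around C4, the right hand around C3. This
event-related desynchronization (ERD) is the physiological contrast every
pipeline here exploits. Lower-limb imagery modulates midline (Cz) rhythms
instead.

## The synthetic generator

`simulate_dataset()` produces labelled epochs as

* a per-channel 1/f ("pink") noise background, synthesized spectrally and
  scaled to a common RMS;
* band-limited oscillations at the mu and beta band centres, generated at
  the focus channels (C3/C4 for hand MI, Cz for lower-limb) as
  amplitude-modulated sinusoids with per-trial random phase and a 1 Hz
  raised-cosine envelope, each rescaled to an exact target RMS;
* spatial spread of each focal oscillation to every other channel with an
  exponential distance decay (space constant 0.35 head radii on the unit
  head circle), which produces focal scalp topographies without a
  volume-conduction forward model;
* the planted effect: the focus channel *contralateral* to the class label
  has its oscillation amplitude multiplied by `1 - erd_depth`. In the
  single-focus (lower-limb) mode the class instead selects which band
  desynchronizes at Cz (class 0 the mu band, class 1 the beta band).

Units are microvolts: the summed rhythm RMS at a focus channel is 5 µV, and
`snr` sets the ratio of that rhythm RMS to the noise RMS (noise RMS
`5/snr` µV). The study configuration used throughout the tests is 300
trials (150 per class), 32 channels, 512 Hz, 4-s trials, `erd_depth = 0.8`,
`snr = 2`; recovery at `erd_depth = 0.9`, `snr = 4` serves as the
easy-separation condition, and `erd_depth = 0` as the null.

The generator is deterministic given `(params, seed)`: every trial draws
from a child seed of the dataset seed, so classes are exchangeable at
`erd_depth = 0` by construction.

What the generator does *not* emulate: volume-conducted noise correlations
between channels (noise is independent per channel), ocular/muscular
artifacts, non-stationarity across a session, and realistic alpha
topographies outside the motor strip. Tests passing on this generator
therefore demonstrate the correctness and statistical calibration of the
pipelines, not their accuracy on real recordings.

## Montages

`generate_montage()` builds schematic 16-, 32- and 64-channel 10/20-derived
layouts on a rectangular row/column grid inside the unit head circle. The
grid makes the "nearest four orthogonal electrodes" of the small Laplacian
well defined: a channel's neighbours are the adjacent occupied positions in
its row and its lateral column. Left/right pairs are mirror-symmetric, so
C3 and C4 sit at ±0.36 head radii.

## Preprocessing

* `downsample()` resamples with a polyphase anti-aliased FIR (from the
  signal package); 2048 → 512 Hz is plain integer decimation. Event indices
  of continuous recordings are rescaled.
* `extract_epochs()` cuts half-open windows `[start, end)` seconds after
  each cue, `sample index = floor(t * fs)`; out-of-bounds trials are
  dropped with a warning.
* `small_laplacian()` subtracts the mean of the orthogonal neighbours from
  each channel; edge channels average over the neighbours they have, and a
  channel with none passes through unchanged. The filter annihilates any
  spatially constant component.
* `standardize()` centres and scales per channel. The default pipelines
  standardize with training-split statistics even though the networks can
  also consume raw microvolts: unscaled inputs survive training only with
  many more optimizer steps, and the flag (`standardize = FALSE`) restores
  literal raw mode. Applying training statistics to test data keeps folds
  honest.

For the MLP branch the order is Laplacian → epoch crop → standardize,
matching the order in which the operations are naturally described for that
pipeline.

## The convolutional decoder

Architecture for a `C x T` epoch (default 32 × 1024, i.e. the [0, 2) s
window at 512 Hz):

1. spatial convolution: 8 kernels of shape `C x 1`, stride 1 — collapses
   the channel axis to 8 learned spatial projections, giving an 8 × 1024
   map;
2. temporal convolution: 40 kernels of shape 8 × 16 with same-length zero
   padding (the stated 8 × 1024 intermediate implies length-preserving
   convolution), giving 40 × 1024;
3. max pooling 1 × 8, non-overlapping (pooled width `floor(T/8) = 128`);
4. dense rectifier layer of 150 units on the 5120-long flattened map
   (component index fastest);
5. 2-unit softmax.

Weights start from N(0, 0.01²), biases at 1 (positive ReLU inputs early
on); training is mini-batch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) on the
cross entropy, with the learning rate divided by 3 whenever the validation
error fails to reach a new minimum for `patience` consecutive epochs and
training terminated after `max_lr_drops` reductions. The validation split
is the final 10% of a seeded shuffle of the training trials; the
best-validation parameters are returned.

Two practical notes, both visible in `train_config()`:

* The default learning rate is 1e-4. At the problem sizes used in the test
  suite (a few hundred trials, so only a handful of Adam steps per epoch),
  that rate needs thousands of steps before the tiny initial weights reach
  useful magnitudes. The simulation experiments therefore run at
  `alpha0 = 1e-2` with small batches — the same architecture and update
  rule, just a schedule that converges within ~50 steps on the planted
  contrast.
* With aggressive rates the rectifier stack can die wholesale (every
  pre-activation below zero); the gradient below the dense head is then
  exactly zero and no recovery is possible. `run_training()` detects a full
  epoch of exactly-zero first-layer gradient and re-initializes from the
  current RNG stream (a deterministic random restart, at most 3 times).

`cnn_channel_importance()` averages the absolute spatial-layer weights
across the 8 kernels. The spatial kernels have no time extent, so averaging
"along the timepoints" reduces to averaging across kernels. On the hand-MI
configuration the importance maximum falls in the C3/C4 neighbourhood in
most seeds once training has converged; on the lower-limb configuration the
class contrast is spectral (mu vs beta at Cz) rather than spatial, every
channel carries a spread copy of the same source, and the spatial layer has
no pressure to localize — its weight maxima are close to uniform over the
scalp. The topography acceptance check documents this honestly rather than
redefining the measure.

## The perceptron baseline

Flattened epochs (channel-major) feed a 1000/300/80 rectifier MLP with a
2-unit softmax. The loss is the binary cross entropy of the class-1
probability — with a two-unit softmax this equals the two-class cross
entropy — plus L2 weight decay `lambda/(2n) * sum(w²)` over weights only,
with `n` the training-set size. Training is mini-batch RMSprop (β = 0.9)
with ε = 1e-8 added inside the square root: the plain recursion divides by
`sqrt(S)` which is zero at the first step. Defaults `lambda = 1e-3`,
`alpha0 = 1e-4` are fixed, reproducible choices standing in for a random
hyperparameter search. Gradients of both networks are validated against
central finite differences at 1e-4 relative tolerance.

On this generator the MLP rarely exceeds chance: discriminating band power
from raw time samples with random oscillation phases is a hard task for a
dense net at these sample sizes, consistent with its role as the weakest
baseline.

## The CSP + multitaper + CVA + SVM pipeline

* **CSP.** Per-class spatial covariances average the trace-normalized
  `X Xᵀ` over trials; the filters extremize the Rayleigh quotient
  `wᵀS₁w / wᵀS₂w`, solved by whitening S₂ and diagonalizing the whitened
  S₁ (a generalized eigendecomposition). Rows are sorted by descending
  eigenvalue, each filter's quotient equals its eigenvalue, and the top and
  bottom `n_pairs = 3` filters are kept. A rank-deficient S₂ receives a
  trace-scaled 1e-8 ridge with a message.
* **Features.** Sliding multitaper PSD: 1-s windows shifted every 62.5 ms
  over the 4-s trial (49 windows), 3 DPSS tapers at time–bandwidth 2,
  log band power averaged into 2-Hz bins over 4–48 Hz. Tapers come from the
  classic tridiagonal eigenproblem and are cached per window length. The
  transform is evaluated only at in-band DFT frequencies via precomputed
  taper-modulated cosine/sine bases, which turns the window loop into BLAS
  matrix products.
* **Ranking.** Two-class canonical analysis; the per-feature discriminant
  power is the diagonal Fisher ratio (between-class over within-class
  scatter). The full canonical direction (the Fisher discriminant — for two
  classes the single canonical variate) is available via
  `cva_rank(direction = TRUE)`. The feature count is either fixed
  (`n_features = 60` of the 132 CSP-space features by default) or chosen by
  a grid search on an inner 80/20 trial split, ties resolved toward fewer
  features.
* **Classifier.** A linear soft-margin SVM (libsvm's SMO through e1071),
  with the primal weight vector, bias and multipliers extracted and the
  sign fixed so positive decisions mean class 1. A Platt-style logistic map
  `sigmoid(a f(x) + c)`, fitted on training decision values by maximum
  likelihood, turns margins into window probabilities.
* **Evidence accumulation.** Per-window probabilities are smoothed by
  `P*(t) = alpha_s P*(t-1) + (1 - alpha_s) p_t` from `P*(0) = 0.5`
  (uninformative prior; the recursion leaves the start value open). The
  trial decision is the first class whose evidence crosses the certainty
  threshold (`alpha_s = 0.95`, `threshold = 0.75` by default, thresholds of
  practical interest lying in 0.70–0.85). A trial in which neither side
  crosses is decided by the final `P*` against 0.5 and flagged as a
  timeout, so accuracy is defined for every trial (accuracy denominators
  include timeouts).

Because features are computed in CSP space by default, scalp maps of
discriminant power use the channel-space mode (`use_csp = FALSE`), where
each channel's score is its mean discriminant power across frequency bins.

## Evaluation

`kfold_cv()` runs stratified 10-fold cross-validation with every fitted
quantity — standardization statistics, CSP filters, rankings, feature
counts, SVM and network weights — estimated inside the training fold only.
The chance level is the smallest accuracy whose exact binomial tail
probability under guessing is at most `alpha = 0.05`; no normal
approximation is used (for 300 trials this is 55%, for 20 trials 75%).
`render_topography()` draws inverse-distance-weighted interpolations of
per-channel scores inside the head circle; the interpolant anchors extremes
at the electrodes and renders deterministically.

## Problem sizes in the shipped experiments

The test-suite experiments use the study configuration above: ten seeded
300-trial datasets for signal recovery, one easy-separation dataset, twenty
60-trial null datasets (16 channels, 160 Hz) for type-I calibration, and
ten seeds per montage for topography recovery. Network runs in these
experiments use the fast schedule (`alpha0 = 1e-2`, batches of 16–32, 6–15
epochs); these sizes give stable pass/fail margins while keeping each
experiment's footprint modest.

## Known limitations

* The generator's independence assumptions (noise uncorrelated across
  channels, stationary envelopes) make CSP's job easier than on real EEG;
  absolute accuracies here do not transfer to real recordings.
* The CNN's channel-importance map is a weight-magnitude heuristic; at high
  learning rates Adam's sign-like steps inflate all weights uniformly,
  which blurs the map unless training continues while gradients still
  carry class information.
* EDF/BDF ingestion is not implemented; the plain-text epoch container
  (`write_epochs()`/`read_epochs()`) is the interchange format, and
  continuous recordings enter through `eeg_recording()`.
* Only two-class problems are supported throughout.
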