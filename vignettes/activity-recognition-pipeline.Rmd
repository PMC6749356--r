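---
title: "Recognising complex activities from smartphone IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising complex activities from smartphone IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(harpipe)
```

## The problem

A waist-mounted smartphone samples its inertial measurement unit (IMU) —
tri-axial accelerometer, gyroscope and magnetometer — at 50 Hz while a
subject goes about a scripted session of twelve activity classes: six static
postures (sitting, standing, four lying positions), five dynamic exercises
(walking, jogging, jumping, stairs up and down), and the labelled
`"transfer"` intervals while the subject reorients between them. The goal is
a classifier that maps a short window of the 9-channel stream to one of the
twelve classes, together with a training-set compression step that makes
refitting the classifier cheap.

`harpipe` implements the whole chain as composable, pipe-friendly verbs:

```
simulate_recording() |> extend_signals() |> segment_recording() |>
  compress_segments() |> select_channels() |> train_dcnn() |>
  evaluate_classifier()
```

plus `run_pipeline()` to execute it end to end from one nested
configuration, and a seeded synthetic generator so that every stage is
testable without access to private recordings.

## Signal extension: 9 to 19 channels

Raw signals are the proper acceleration $S_\alpha$ (m/s$^2$), angular
velocity $S_\beta$ (rad/s) and magnetic field $S_\gamma$ (µT). Four derived
signal groups are appended, giving 19 channels in a fixed order
(`extended_channels()`):

* **Gravity / linear-acceleration split.** A third-order low-pass elliptic
  (Cauer) filter, applied zero-phase (forward and backward), estimates the
  quasi-DC gravity component; the residual $S_{\alpha 1} = S_\alpha -
  \hat g$ is the linear acceleration. By construction the two components
  recompose to the input exactly. Defaults: cutoff 0.3 Hz (the low end of
  the admissible 0.3–20 Hz range — gravity is quasi-DC), passband ripple
  0.01 dB, stopband 60 dB. Because the filter runs forward and backward,
  the effective magnitude response is the *square* of the designed one and
  there is no group delay.
* **Elementwise absolute acceleration** $S_{\alpha 2} = |S_\alpha|$,
  reducing sensitivity to device orientation flips.
* **Angular-velocity sum** $S_{\beta 1} = S_{\beta x} + S_{\beta y} +
  S_{\beta z}$, a cheap scalar summary that separates gait-like activities.
* **Orientation** $S_\delta$: roll/pitch/yaw (radians, intrinsic Z-Y-X)
  from a 9-axis attitude-and-heading (AHRS) fusion.

### Numerical notes on the zero-phase filter

The obvious implementation (zero-padded forward–backward filtering) leaves
start-up transients of order $10^{-2}$ m/s$^2$ that decay over seconds when
the cutoff is 0.3 Hz. `harpipe` therefore applies the filter
MATLAB-`filtfilt`-style: the series is extended at both ends by
odd reflection (continuous in value and slope) and each pass starts from
steady-state initial conditions, so a constant input passes through exactly
(to ~$10^{-12}$) and edge transients stay local. The first and last second
of every extended recording are still flagged (`edge_samples` attribute)
and the segmenter avoids them by default.

### The AHRS fusion

Orientation is estimated by a gradient-descent complementary filter in the
Madgwick family: the unit quaternion $q$ (sensor frame → earth frame) is
propagated by gyroscope integration, $\dot q = \tfrac12\, q \otimes
(0,\omega)$, and corrected by descending the measurement objective

$$ f(q) = \begin{bmatrix} R(q)^\top e_3 - \hat a \\ R(q)^\top b(q) - \hat m
\end{bmatrix}, $$

where $e_3$ is earth "up", $\hat a$, $\hat m$ are the normalised
accelerometer and magnetometer readings, and $b(q) = (b_x, 0, b_z)$ is the
earth-frame magnetic reference recomputed from the current estimate, so
magnetic declination is absorbed into yaw rather than fought. The gain
(default 0.1 rad/s) is the rate at which the estimate is pulled toward the
measured directions; at 50 Hz it corrects a 20° initialisation error within
a few seconds while keeping gyro noise suppressed. One implementation
choice: the Jacobian of $f$ is evaluated by central differences rather than
the usual hand-expanded algebra — at the fusion-gain scale the two are
numerically indistinguishable, and the objective stays in one readable
place. Samples with a zero-norm accelerometer reading skip the correction
step and are reported.

Whether orientation should be reported in radians or degrees is a
convention choice; `harpipe` uses radians throughout.

## Windowing, compression, channel selection

The 19-channel stream is cut into fixed windows of `ld = 150` samples (3 s
at 50 Hz), non-overlapping by default (`stride = ld`; overlap is a free
parameter, not a default, because it multiplies near-duplicate windows).
Window labels come from the per-sample labels by a majority rule, ties
broken by the earliest-occurring label; a stricter purity rule (drop
windows whose modal label covers < 80%) is available. How to label a window
that straddles a transition is genuinely open; majority is the least
surprising default and the transfer class absorbs most of the ambiguity.

**Compression.** Within each label class, flattened windows are compared by
cosine similarity $\rho = \langle a, b\rangle / (\lVert a\rVert\,\lVert
b\rVert)$; a single greedy pass in original order drops a window when its
similarity to an already-retained window reaches the threshold (default
0.99). Two windows with $\rho$ *near 1* are near-duplicates, so the
threshold acts as a lower bound (the comparison direction is configurable).
The compression degree $\zeta \in (0, 1]$ bounds the effect: at least
$\lceil \zeta L \rceil$ of a class's $L$ windows are always retained
($L^* = \zeta L$), classes are never emptied, and with `force_zeta = TRUE`
the least-distinct retained windows (highest similarity to the rest) are
additionally dropped until the target is met exactly — that mode is what a
fixed "remove 50%" experiment uses. Cross-label pairs are never compared,
and compression operates on the 19-channel windows (before channel
selection), where duplicates are easiest to recognise.

**Selection.** Four presets reproduce the classifier-input comparison:
`acc` (3 channels), `acc_gyro` (6), `acc_gyro_mag` (9 raw), and `our` — the
processed 9: linear acceleration (3), absolute acceleration (3), the
angular-velocity sum (1), and the pitch and yaw orientation channels. Pitch
and yaw are the informative pair here (roll is degenerate for several lying
postures); the pair is configurable.

## The classifier

A compact 2D convolutional network treats each $m \times L_d$ window as a
one-channel image. Four convolutional modules — 3×3 valid convolution,
batch normalisation, ReLU; the last module adds max-pooling — are followed
by dropout (0.5), one fully-connected layer and softmax. With valid 3×3
kernels the feature map after module $k$ is $(m - 2k) \times (L_d - 2k)$;
for the `our` preset ($9 \times 150$) that is $7\times148$, $5\times146$,
$3\times144$, $1\times142$. Max-pooling spans the full remaining channel
axis with a width-2, stride-2 temporal window. Filter counts default to
5/10/15/20 per module; both depth and filters are configurable (an input
must satisfy $m > 2\,n_\text{modules}$).

Training uses Adam (learning rate 0.001, dropped by a factor 0.1 every 100
epochs) on categorical cross-entropy. Inputs are z-scored per channel with
training-set statistics stored in the fitted model. Batch size defaults to
50 and epochs to 60; the acceptance experiments below use 10 epochs, which
is already past the loss plateau on the synthetic data. Initialisation,
shuffling and dropout are driven by one seed, so a fitted model is
bit-reproducible. Everything is implemented in the package (convolution
forward/backward in compiled code via im2col + GEMM; batch-norm, pooling,
dropout, Adam in vectorised R) and the backward pass is verified against
central finite differences in the test suite.

## Evaluation

`evaluate_classifier()` returns the confusion matrix in vocabulary order
with a row summary (per-class recall, %) and a column summary (per-class
precision, %), rendered with one decimal; accuracy is trace/total, and
"error" always means 1 − accuracy. `split_segments()` supports the two
split styles used in practice: chronological (first 80% train / last 20%
test) and subject-wise (hold out whole subjects, e.g. 18 train / 2 test);
which style a study means is often ambiguous, so both are first-class.
`zeta_sweep()` re-runs compress → train → evaluate over a grid of $\zeta$
with `reps` seeds and reports the median and 0.25–0.75 quartile band of the
errors. Training time is reported nowhere as a quality measure — it is
hardware-bound.

## The synthetic generator

`simulate_recording()` emulates the collection session: a rigid device at a
posture-dependent orientation. Static postures differ by the gravity
direction in the device frame (the four lying postures put gravity along
±x/±y; `lying-left`/`lying-right` are antiparallel); dynamic exercises add
sinusoidal oscillations (fundamental plus a 0.3-weighted first harmonic)
with activity-specific frequency and per-axis amplitudes; the magnetometer
sees a fixed earth field — default (22, 5, −42) µT — rotated into the
device frame; transitions are constant-rate slerp reorientations labelled
`"transfer"`, with the exact body angular velocity on the gyroscope.
Gaussian noise is added per sensor (0.25/0.35 m/s², 0.03/0.05 rad/s,
0.6/0.8 µT for static/dynamic classes). The default protocol follows the
published session order — three sit/stand alternations, three jump/jog
blocks with standing breaks, the four lying postures twice, three
walk/upstairs/downstairs blocks — with 50 s main bouts, 15 s breaks and
2.5 s transitions: ~30 min and ~90,000 samples per subject, matching the
stated "about one minute per activity, 25–30 min, >5×10⁴ samples" session.
Cohorts are emulated by seeded per-subject jitter: log-normal perturbation
of oscillation frequency (σ = 0.04) and amplitudes (σ = 0.08) and a small
random posture tilt (σ = 3°).

What the generator deliberately does **not** model: biomechanical gait
shape, soft-tissue artifacts, sensor bias/drift, magnetic disturbances, or
subjects whose device placement differs qualitatively. Passing tests on
this data therefore demonstrate that the pipeline machinery is correct and
that the classifier can exploit the designed signal structure — they do not
certify accuracy figures on real recordings.

## Problem sizes used by the shipped experiments

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to keep a desk run comfortable:

* End-to-end recovery: the full default cohort — 20 subjects, 18/2
  subject-wise split, `our` preset, $\zeta = 0.5$ with forced target — at
  10 training epochs (~10,000 training windows before compression).
* Compression-degree sweep: $\zeta \in \{0.1, 0.5, 0.9\}$, 20 repetitions,
  on a stratified subsample (25 windows per class) of the training set,
  testing on one held-out subject at 6 epochs. The subsample keeps 60
  trainings affordable; the qualitative contrast — less retained data,
  higher test error — is what the sweep is for.
* Greedy-compression oracle: exhaustive $O(L^2)$ brute force on ≤ 50
  windows across 100 random seeds.

## Known limitations

* The AHRS absorbs magnetic declination into a constant yaw offset; yaw is
  therefore only meaningful relative to the session's own frame.
* Euler angles are near-singular when gravity aligns with the device x
  axis (two of the lying postures); pitch saturates at ±90° and yaw/roll
  become noisy there. The classifier tolerates this; downstream users of
  the raw angles should prefer the quaternion attribute.
* The compression pass is greedy keep-first; it is deterministic and
  matches an exhaustive pairwise oracle on the same rule, but it is not a
  globally optimal coreset.
* Batch-norm statistics come from minibatches of the compressed training
  set; with very small classes and tiny batch sizes the running estimates
  get noisy — batch size 50 against ≥ 10 windows per class is comfortable.
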