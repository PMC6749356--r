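# harpipe

Human activity recognition from smartphone IMU signals: a complete,
reproducible R pipeline for classifying twelve complex activities — six
static postures (sitting, standing, four lying positions), five dynamic
exercises (walking, jogging, jumping, stairs up/down) and the `transfer`
intervals between them — from a waist-mounted phone's 9-channel inertial
stream (tri-axial accelerometer, gyroscope, magnetometer at 50 Hz).

It is aimed at researchers in wearable sensing / digital health who want a
transparent, fully seeded implementation of this kind of pipeline, including
a synthetic data generator so everything runs without access to private
recordings.

## What it does

1. **Signal extension (9 → 19 channels).** A third-order zero-phase low-pass
   elliptic filter splits raw acceleration S<sub>α</sub> into gravity and
   linear acceleration S<sub>α1</sub> = S<sub>α</sub> − ĝ; elementwise
   absolute acceleration S<sub>α2</sub> = |S<sub>α</sub>|; the
   angular-velocity sum S<sub>β1</sub> = S<sub>βx</sub> + S<sub>βy</sub> +
   S<sub>βz</sub>; and orientation S<sub>δ</sub> (roll/pitch/yaw) from a
   gradient-descent 9-axis AHRS fusion:

   S = [S<sub>α</sub>, S<sub>β</sub>, S<sub>γ</sub>] ⇒
   S\* = [S<sub>α</sub>, S<sub>β</sub>, S<sub>γ</sub>, S<sub>α1</sub>,
   S<sub>α2</sub>, S<sub>β1</sub>, S<sub>δ</sub>]

2. **Sliding-window segmentation** into labelled m × L<sub>d</sub> windows
   (default L<sub>d</sub> = 150 samples = 3 s at 50 Hz).

3. **Training-set compression.** Within each label class, near-duplicate
   windows (cosine similarity ρ = ⟨a,b⟩/(‖a‖‖b‖) ≥ 0.99) are pruned by a
   greedy pass, bounded by the compression degree ζ: at least ⌈ζ·L⌉ of L
   windows are retained (L\* = ζ·L); with `force_zeta = TRUE` the target is
   hit exactly. ζ = 0.5 removes 50% of each class.

4. **Channel selection.** Presets `acc` (3), `acc_gyro` (6),
   `acc_gyro_mag` (9 raw) and `our` (the processed 9: S<sub>α1</sub>,
   S<sub>α2</sub>, S<sub>β1</sub>, S<sub>δY,Z</sub>).

5. **A compact 2D CNN**: four modules of 3×3 valid convolution + batch norm
   + ReLU (max-pooling in the last), dropout 0.5, fully-connected + softmax;
   feature map after module k is (m − 2k) × (L<sub>d</sub> − 2k). Trained
   with Adam (lr 0.001, ×0.1 every 100 epochs), fully seeded.

6. **Evaluation**: confusion matrices with per-class recall/precision
   summaries, chronological and subject-wise splits, and a ζ-sweep with
   median/quartile bands over repeated training runs.

A seeded synthetic generator (`simulate_recording()`,
`simulate_subjects()`) emulates the scripted collection session (~30 min,
~90,000 samples per subject) with posture-dependent gravity directions,
activity-specific oscillations, slerp transitions and per-subject
parameter jitter. See the methods vignette
(`vignettes/activity-recognition-pipeline.Rmd`) for the model, parameter
meanings and limitations.

## Worked example

```r
library(harpipe)

cfg <- pipeline_config(
  seed = 42,
  simulate = list(n_subjects = 6L, bout_duration = 30, break_duration = 10),
  split = list(method = "subject", train_fraction = 0.83,
               n_test_subjects = 1L),
  dcnn = list(epochs = 10L, batch_size = 32L)
)
res <- run_pipeline(cfg)
#> simulate: 6 subjects, seed 42
#> preprocess + segment: ld = 150, stride = 150
#> segmented: 2250 segments
#> compressed training set: 1875 -> 938 segments
#> train: 10 epochs on 938 segments (our preset)
#> test accuracy: 77.60%

glance(res$report)
#> # A tibble: 1 × 4
#>   accuracy error n_test n_classes
#>      <dbl> <dbl>  <int>     <int>
#> 1    0.776 0.224    375        12

head(tidy(res$report), 5)
#> # A tibble: 5 × 6
#>   class n_true n_predicted recall_pct precision_pct zero_denominator
#>   <chr>  <int>       <int>      <dbl>         <dbl> <lgl>
#> 1 sit       30          30      100           100   FALSE
#> 2 stand     83          91      100            91.2 FALSE
#> 3 jump      30          32      100            93.8 FALSE
#> 4 jog       30          17       56.7         100   FALSE
#> 5 walk      30          34      100            88.2 FALSE
```

Reading: one held-out subject (375 windows) is classified at 77.6% with a
938-window training set (six subjects, 30 s bouts, ζ = 0.5 compression,
10 epochs; ~80 s on one CPU). `tidy()` gives the per-class row summary
(recall, %) and column summary (precision, %) of the confusion matrix;
`autoplot(res$report)` draws it. At the full default scale —
`run_pipeline(pipeline_config(seed = 1))`, 20 subjects with ~50 s bouts,
an 18/2 subject split and 10 epochs — the same chain reaches 97.8%
held-out accuracy in about 3.5 minutes.

Each stage is also an ordinary function on tibbles, so the chain can be
driven stepwise (`simulate_recording() |> extend_signals() |>
segment_recording() |> ...`), and `exec/harpipe` exposes the stages as
shell subcommands (`simulate`, `preprocess`, `segment`, `compress`,
`select`, `train`, `predict`, `evaluate`, `sweep`, `run-all`).

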