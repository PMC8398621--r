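---
title: "Estimating knee joint angle from insole plantar pressure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating knee joint angle from insole plantar pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneegait)
```

## The problem

Knee kinematics during walking are usually measured with camera systems or
goniometers — accurate, but demanding in space, setup and operator skill. An
instrumented insole is far easier to wear. `kneegait` implements a complete
pipeline that regresses the knee joint angle over a gait cycle from the
*total plantar pressure* measured by a 10-channel textile capacitive insole,
and quantifies how well that works across three shoe types — flat (S1),
sneaker (S2), stiletto heel (S3) — and two self-selected treadmill speeds,
comfortable (C, ~2.4 km/h) and fast (F, ~5.1 km/h).

The pipeline has five stages, each a package module:

1. **Sensor model** — physics and calibration of the capacitive pressure
   sensor.
2. **Synthetic data** — a generator for paired pressure/angle trials with
   known ground truth, so every later stage is testable without human data.
3. **Preprocessing** — trimming, denoising, Zero-To-Zero gait-cycle
   segmentation, 100-point time normalization.
4. **Regressor** — a four-layer perceptron (and a 1-D CNN comparison)
   trained with RMSprop under leave-one-subject-out validation.
5. **Evaluation** — RMSE, mean relative error, correlation efficiency,
   Bland-Altman agreement and knee-flexion phase patterns.

## Sensor model

The transducer is a parallel-plate capacitor with a nonwoven fabric
dielectric: `C = eps_r * eps_0 * A / d`. Loading compresses the dielectric
and raises the capacitance. The calibration curve maps pressure to relative
capacitance change `dC/C0` piecewise linearly: sensitivity 0.232 MPa^-1 up
to the 11.00 kPa breakpoint and 0.070 MPa^-1 above it (the textile
saturates under load). We define sensitivity as the slope of relative
capacitance change per unit pressure — the standard convention for
capacitive pressure sensors; the curve is continuous, strictly increasing,
and therefore exactly invertible, which is how capacitance counts become
kPa. The dielectric's relative permittivity is not critical — it cancels in
the relative change — and defaults to 1.2, typical of loose nonwoven
fabric.

Working pressures are set by body weight over the insole area: an 80 kg
subject fully supported on the minimal 23.5 cm x 8.0 cm stress area gives
`P = 784.8 N / 0.0188 m^2 = 41.74 kPa`, which fixes the tens-of-kPa scale
used throughout.

```{r sensor}
pressure_from_force(80 * 9.81, 0.235 * 0.08)
relative_capacitance_change(c(5, 11, 21))
```

## What the synthetic cohort emulates — and what it does not

`make_cohort()` draws subjects from the study population statistics: young
women of 50.4 ± 2.2 kg walking at 2.40 ± 0.30 km/h (comfortable) and
5.10 ± 0.20 km/h (fast). Quantities the protocol does not report are set
once to physiologically plausible values and documented here:

* **Cadence**: ~42 strides/min at comfortable and ~56 strides/min at fast
  speed (SD 3), consistent with treadmill walking at those speeds.
* **Range-of-motion multiplier** (`rom_scale`): truncated normal, mean 1,
  SD 0.05, bounds [0.9, 1.1] — inter-subject variation of peak swing
  flexion of about ±5%, typical for healthy adults.
* **Sensor noise** (`noise_sd`): 0.3–0.6 kPa per channel at full load.

Each trial tiles 100-point, heel-strike-referenced templates at the
subject's cadence with ±3% per-cycle duration jitter:

* The **angle template** (Kinovea convention, 180° = full extension) is a
  sum of raised-cosine bumps: a loading-response flexion wave peaking near
  15% of the cycle, a pre-swing build-up, and the main swing flexion peak
  near 72%. Bumps wrap circularly across the cycle boundary so consecutive
  strides join smoothly. Fast gait widens the swing peak amplitude by ~8%;
  each centimetre of heel height removes ~0.6° of it (a stiff-knee
  tendency in high heels).
* The **pressure template** is stance-only (samples 1–60; swing is exactly
  zero) and carries the classic double bump: a heel-strike peak loading
  the rearfoot channels and a push-off peak loading the forefoot, over a
  broad mid-stance base. Heel height softens and advances the heel-strike
  peak, strengthens and delays push-off, and shifts load toward the
  forefoot — so each shoe leaves a recognizable signature in the summed
  signal. Amplitudes scale with body weight over the insole area and rise
  ~15% at fast speed. The 10 channels split 4 forefoot / 2 midfoot /
  4 rearfoot.
* The stance envelope uses smoothstep edges so that its spectral content
  stays below the 15 Hz analysis filter, while the very first stance
  sample still clears the segmentation threshold — contact onset remains a
  detectable step.
* **Noise** has three parts, all applied to pressure only: load-
  proportional Gaussian noise, a >20 Hz treadmill-vibration tone pair
  (27 and 33 Hz) coupled through contact, and a small constant noise floor
  (0.05 kPa). Noise in the unloaded swing phase must stay near zero:
  capacitive sensors genuinely have a tiny noise floor when unloaded, and
  a large additive component clipped at 0 kPa would lift the swing
  baseline above any sensible zero-threshold and make pressure-based
  segmentation physically impossible.

The generator is *not* a musculoskeletal simulation. It does not model
ground-reaction-force vectors, shear loading, double support asymmetries,
fatigue or footwear wear-in; subject differences reduce to weight, speed,
cadence, ROM and noise level. Passing tests therefore show that the
pipeline recovers the structure this generator encodes — they do not prove
performance on real insole recordings.

## Preprocessing decisions

The chain is: trim to the centred minute → 10-point moving average →
4th-order 15 Hz Butterworth → channel sum → Zero-To-Zero segmentation →
30 cycles → 100-point resampling → heel-strike re-referencing → min-max
scaling. Decisions that the chain's description leaves open:

* **Zero threshold.** Real signals never return to exactly zero, so "zero"
  defaults to 2% of the trial's 95th-percentile total pressure — scale-free
  and robust to the noise floor.
* **Zero-phase filtering.** The Butterworth filter is applied
  forward–backward with odd-reflection padding and steady-state initial
  conditions, so constants pass through exactly and gait events are not
  delayed (segmentation depends on their timing). A causal single-pass mode
  is available.
* **Moving average.** Trailing (causal) with partial leading windows; the
  trimmed margins make the edges irrelevant. A trailing mean does delay
  threshold crossings by a few samples; both cycle boundaries shift
  together, so extracted cycles remain internally consistent, and in
  noise-free verification runs the window is set to 1 (no smoothing is
  needed without noise, and this keeps recovered boundaries within one
  sample of ground truth).
* **Heel-strike re-referencing.** A Zero-To-Zero segment runs toe-off to
  toe-off; the heel strike inside it is found by the same threshold rule
  and the resampled cycle is circularly rotated so it starts there, with
  the stance fraction recorded. No fixed 60/40 split is assumed, though
  60% is what the generator produces by construction.
* **Angle pairing.** Pressure and angle streams share the trial clock;
  angle cycles are sliced at pressure-derived heel-strike times on the
  standard half-open normalization grid (sample 1 = heel strike, sample
  101 would be the next heel strike) and interpolated with cubic splines —
  the 30 Hz video stream is sparse relative to the 100-point grid and the
  knee trajectory is smooth.

## The regressor

The network is a fully connected 100–250–150–100 perceptron: hidden layer 1
uses the logistic activation, hidden layer 2 ReLU, and the output layer ELU
(alpha 1, the conventional value). Inputs are min-max-normalized total
pressure cycles, targets min-max-normalized angle cycles; normalization
parameters are fitted per model on its training rows only and stored with
the model. One printed form of the logistic function in the source
material, `1/(1 - e^h)`, is singular at `h = 0`; the function is named
Sigmoid throughout, so we implement the standard `1/(1 + e^-h)` and treat
the printed form as a sign error.

Training minimizes mean squared error with mini-batch RMSprop: learning
rate 0.007 (as specified), decay 0.9 and epsilon 1e-8 (conventional
defaults), 50 epochs, batches of 32 — mirroring the stated protocol of the
convolutional comparison model for comparability. Validation follows
leave-one-subject-out: each fold withholds one training subject from the
gradient updates and records its loss per epoch; folds rotate through the
training subjects and final weights are taken from the last epoch (no early
stopping). Every random draw — cohort, noise, initialization
(Glorot-uniform), batch shuffling, dropout — derives from one seed, so runs
are bit-for-bit reproducible.

Six dataset combinations define the models: M1–M3 train on a single shoe at
both speeds (300 cycles with 5 training subjects), M4–M5 on all shoes at
one speed (450), and M6 on everything (900). Predictions are de-normalized
and then smoothed with a zero-phase 4th-order Butterworth at 0.2
cycles/sample on the 100-point grid, restoring the input's frequency
content after the network.

The CNN comparison stacks Conv1D(32, kernel 3, sigmoid) → max-pool 2 →
Conv1D(64, kernel 3, ReLU) → max-pool 2 → 50% dropout → dense ELU → linear
output, trained identically. It exists only to show that the two families
give similar accuracy on this task; kernel and pooling sizes printed as
"3 × 3" and "2 × 2" are read as lengths 3 and 2 for 1-D convolutions.

## Evaluation

With `x` the prediction and `y` the actual angle (both in degrees over a
100-point cycle):

* `RMSE = sqrt(mean((x - y)^2))`
* `MRE = mean(|x - y| / |x|)` — the denominator is the *prediction*, as
  defined; the form is asymmetric and we keep it, since angles in the
  Kinovea convention are far from zero. The test suite asserts this literal
  behavior.
* `R = 1 - sum((y - x)^2) / sum((y - mean(y))^2)` — a coefficient-of-
  determination form ("correlation efficiency"); it is not a Pearson
  correlation, so the Pearson coefficient is logged alongside for
  diagnostics.

Metrics are computed per cycle and averaged over the 30 test cycles of each
model × shoe × speed cell. Bland-Altman agreement uses one point per test
cycle (the cycle's mean difference, estimate − actual), with limits of
agreement at bias ± 1.96 sample standard deviations. Knee flexion is
reported as 180° − angle with stance at 0–60% and swing at 60–100% of the
cycle.

## Numerical choices and degenerate inputs

* Min-max scaling refuses constant training data; its inverse is exact to
  machine precision.
* Segmentation returns an empty event list rather than failing on silent
  series; cycle extraction reports how many events it found when there are
  too few, and rejects segments whose duration deviates more than 40% from
  the median (artifact guard) before choosing the 30 consecutive segments
  nearest the window centre.
* Cycle resampling preserves endpoints and is exact on affine inputs;
  rotation requires at least one suprathreshold sample ("no contact"
  otherwise).
* The MRE raises an error on zero predictions rather than returning Inf.
* Gradients of both networks are verified against central finite
  differences in the test suite.

## Problem sizes

The default experiment — 7 subjects × 6 conditions × 2-minute trials,
30 cycles each, six models trained for 50 epochs with rotating LOSO
validation — runs in about a minute on one CPU core. The test suite uses
the same cohort size, a 1,500-sample linear-map dataset for the
learnability check, and a 600-sample gait-shaped dataset for the ANN-vs-CNN
comparison (with a single validation fold for the CNN, whose hand-rolled
convolutions dominate runtime).

## Known limitations

* Total pressure discards the spatial channel pattern before regression;
  per-channel inputs might disambiguate shoes better, but the pipeline
  deliberately mirrors the summed-signal design.
* Swing-phase angles are predicted from a signal that is identically zero
  during swing; the network learns the condition-specific swing shape from
  stance context, which is why cross-shoe generalization (e.g. models
  trained without stilettos predicting stiletto gait) shows the lowest R.
* The piecewise sensor calibration is taken as given; raw bench data to
  re-fit it are not available.
* Shear stress under high heels, sensor hysteresis and temperature drift
  are not modelled.

## A worked run

```{r run, eval = FALSE}
experiment <- run_experiment(experiment_config(seed = 1))
experiment$report$metrics    # 36 rows: model x shoe x speed
experiment$report$agreement  # Bland-Altman per model
```
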