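---
title: "Estimating oxygen uptake from gait and heart rate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating oxygen uptake from gait and heart rate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vo2net)
```

## The estimation problem

Oxygen uptake (V̇O2, ml·min⁻¹·kg⁻¹) is the standard measure of movement
economy in walking and running, but direct measurement requires a portable
spirometer. `vo2net` implements the indirect route: estimate V̇O2 from
step-wise gait features (speed, peak-to-peak speed change, step duration,
vertical oscillation, all computable from a wearable inertial/GPS unit) plus
heart rate, using neural-network regressors. Two settings are covered:

* **intra-subject** estimation — train and test on (disjoint parts of) the
  same person's session, with a many-to-one LSTM regressor;
* **inter-subject** estimation — leave-one-subject-out (LOSO): the network
  never sees the test subject, optionally receiving four categorical
  participant attributes (age, BMI, sex, fitness class) through a small
  side branch.

Because no public dataset with this exact sensor suite exists, the package
ships a synthetic-cohort generator that reproduces the statistical structure
such a field study produces, so that every downstream stage — preprocessing,
training, evaluation — is testable end to end.

## The synthetic cohort

### Protocol and kinetics

Each simulated participant rests seated for 5 min, then completes up to
eight 5-min walk/run bouts (speeds 1.0, 1.3, 1.5, 2.2, 2.5, 2.8, 3.1,
3.3 m/s; the first bout always 1.0 m/s, the rest in random order), each
followed by 5 min of seated rest. V̇O2 and heart rate follow single-
compartment first-order on/off kinetics toward speed-dependent steady
states,

$$\frac{dX}{dt} = \frac{X_{ss}(v) - X}{\tau},\qquad
\tau = \tau_{on} \text{ if } X_{ss} > X \text{ else } \tau_{off},$$

integrated exactly on a 1 Hz grid (the discrete update
$X_{t+1} = X_{ss} + (X_t - X_{ss})e^{-1/\tau}$ is the exact solution for a
constant target, so the simulated trajectory equals the piecewise
exponential closed form — the kinetics test exploits this). Steady-state
V̇O2 is quadratic in speed, $\dot VO_{2,ss} = r + a v + b v^2$, capturing
the mild nonlinearity of running cost; the heart-rate steady state is
linear in speed, capped at 220 − age. Asymmetric time constants
($\tau_{off} > \tau_{on}$ on average) make onset and recovery
distinguishable.

Latent parameters are drawn per subject from truncated normal
distributions; observable attributes match the published cohort statistics
of the 16-participant study this design emulates (pooled age
27.5 ± 3.5 yr, height 175.3 ± 8.4 cm, mass 71.8 ± 12.9 kg; 8 of 16 female;
10 of 16 trained, with fitness-specific subgroup means). Fitness lowers
resting heart rate and shortens $\tau_{on}$, as training adaptation does.

### Sensor streams and their defects

The generator emits three asynchronous streams: V̇O2 every 5 s (with a
uniform ±30 s clock offset, kept as ground truth for the synchronization
oracle), heart rate at 1 Hz, and one record per step during locomotion.
Observation noise follows the sensor accuracies the emulated hardware
quotes — ±0.05 m/s speed, ±1 cm vertical oscillation, ±10 ms step duration,
read as 2-sigma bounds — plus documented guesses where no figure exists
(2 bpm heart rate, 1.5 ml·min⁻¹·kg⁻¹ V̇O2; breath-by-breath V̇O2 is noisy,
which is why the study smooths it). Three data defects seen in the real
campaign are reproduced by default on subjects 1, 2 and 10: a long span of
missing heart-rate data, a ~90 s spirometer gap, and termination after the
fifth cycle.

### Engineered correlation structure

Two features are deliberately engineered rather than naively simulated:

* **Vertical oscillation** has walking and running regime levels
  (≈3.3 cm and ≈9.5 cm) with a negative within-run slope, near-zero
  oscillation for the sparse postural "shuffle" steps emitted during seated
  rest, and a rare heavy-tailed spike component (3% of steps, exponential
  with 0.5 m mean) representing inertial-integration artifacts. The spikes
  destroy the *linear* correlation with V̇O2 while leaving ranks intact,
  reproducing the striking observation that motivates reporting Spearman
  alongside Pearson coefficients: ρ ≈ 0.55–0.6 versus r ≈ 0.2 pooled.
* **Step duration** has a sex-dependent relation to speed (cadence slope
  positive for simulated males, negative for females), so its correlation
  with V̇O2 flips sign between sex subgroups while staying weak pooled —
  giving the subgroup correlation analysis a real contrast to detect. This
  is an engineered contrast, not a biomechanical claim.

What the generator does **not** emulate: raw 400 Hz inertial signals, gait
biomechanics (the step segmentation of the upstream hardware is assumed
done), anaerobic-threshold effects, day-to-day drift, or weather. Passing
tests therefore demonstrate that the pipeline recovers structure *of this
kind*; they do not certify accuracy on real field data.

## Preprocessing

Mirrors the emulated study's pipeline:

1. **Smoothing.** V̇O2: Savitzky–Golay filter, polynomial order 3 (9 for
   unusually noisy subjects), applied three times. The filter window must be
   odd and exceed the order; the package default is 11 samples, the
   smallest round odd window comfortably above both polynomial orders.
   Heart rate: centered moving average, window 3 (5 for noisy subjects),
   edges handled by symmetric shrinking.
2. **Synchronization.** Both streams are interpolated to a common 1 Hz
   grid, standardized, and cross-correlated over integer lags within
   ±120 s (physiological clock offsets are small); the arg-max lag is the
   offset estimate, ties breaking toward the smallest absolute lag for
   determinism. On 200 simulated sessions the estimate lands within 2 s of
   the injected truth in well over 95% of cases.
3. **Resampling.** V̇O2 and heart rate are linearly interpolated onto step
   start times (linear interpolation is the simplest monotone-preserving
   scheme at these rates; whether the original pipeline interpolated or
   nearest-neighbour-matched is not documented). Steps whose interpolation
   bracket spans a data gap (spacing > 1.5× nominal) are dropped, not
   imputed, mirroring the study's removal of the spirometer-gap period.
4. **Windowing.** Sequences of L = 50 or 200 consecutive steps form the
   5×L network inputs; the target is the V̇O2 at the window's final step
   (many-to-one, causal). Windows never cross subject boundaries but may
   span walk/run/rest transitions. The stride is configurable (default 1,
   maximally overlapping).
5. **Normalization.** Per-feature mean/SD computed on training subjects
   only and stored with their subject-ID provenance, so leave-one-subject-
   out leakage can be audited mechanically.

## Network families

All families are built on a small hand-written engine (dense, 1D
convolution via im2col, depthwise-separable convolution, batch
normalization, max/average/adaptive pooling, RNN/LSTM/GRU cells with
backpropagation through time, sinusoidal positional encoding), with
gradients verified against finite differences in the test suite. The
inter-subject architecture is dual-branch: a regression head consumes the
5×L temporal matrix; an optional attribute head (single 4→2 fully connected
layer + ReLU, 10 parameters) consumes the category codes; their
concatenation passes through a family-specific join (no hidden layer for
recurrent/CNN heads, a 4-unit ReLU layer for DenseNet, 16 units for
ResNet/Xception) to the scalar estimate.

* **Baseline LSTM** (intra-subject): one LSTM layer of 150 units, dense
  output; Adam, constant learning rate 0.005, 1000 epochs.
* **Modified LSTM**: 100 units; learning rate 0.005 decayed ×0.2 after 25
  epochs without validation improvement (floor 10⁻⁶); training additionally
  stops early when the trailing 20 epochs contain no run of three epochs
  with strictly decreasing |train − validation| loss gap. The gap is read
  as a generalization-gap monitor; strict decrease makes the rule
  deterministic.
* **RNN/LSTM/GRU heads**: three stacked layers of 128 units (per
  direction), output = final-time-step top-layer state (128, or 256
  bidirectional).
* **CNN head**: three 1D convolutions (kernel 3, filters 32/64/32) with
  batch norm + ReLU, then a fully connected layer to 16 or 32 units.
* **ResNet head**: three residual blocks of three convolutions each
  (kernels {3,3,3} or {7,5,3}; filters 24/48/48), 1×1 projection shortcuts
  on channel mismatch, global average pooling, output width 16.
* **DenseNet head**: stride-2 input convolution to 24 channels at half
  length; four dense blocks (sinusoidal positional encoding, four modules
  of a 1×1 then kernel-3 convolution with 16 filters, additive module
  shortcut, dense concatenation across modules: +64 channels per block);
  halving max pools after the first three blocks so the final map sits at
  ~L/16 with 24 + 4·64 = 280 channels; two 1×1 convolutions reduce 280 →
  32 → 16; flatten. The printed temporal bookkeeping of the source design
  (initial L/2 map, a halving "after every block", final L/16) is
  arithmetically inconsistent; this build halves in three of the four
  blocks, which lands exactly on the printed final length, and uses floor
  division so any L ≥ 16 (including 50 and 200) builds. Within a module
  "add" and across modules "concatenate" resolves the source's ambiguous
  wording the only way both statements can hold at once.
* **Xception head**: stacked modules combining three depthwise-separable
  convolutions (kernels 3/5/7 — several kernel scales per module, which is
  the stated point of the design; n_f = 8 or 16 filters) with a stride-1
  max-pooling path and an additive residual shortcut; adaptive average
  pooling to 4 bins, then a fully connected layer to c_out = 16 or 32. The
  module count is not printed in the source design; three modules
  (matching the depth of the other heads at this data scale) is the
  default, configurable.

Inter-subject training uses AdamW (decoupled weight decay 0.01 on weight
matrices only) with a cosine schedule from 10⁻³ to 10⁻⁵, batch size 64,
mean-squared-error loss (the natural pairing for an RMSE-reported metric;
the loss is not stated in the source design), and checkpointing at the best
validation loss — without it the two validation subjects would serve no
purpose at the 100-epoch budget. **Targets are standardized** with
training-set mean/SD and unscaled at prediction; input-only normalization
with raw ml·min⁻¹·kg⁻¹ targets would require the output layer to traverse
~20 units at learning rates of 10⁻³, which no scaled epoch budget can do.
This is a deliberate design choice of this package, leakage-free because
the statistics come from training folds only.

## Evaluation machinery

* **Intra-subject splits**: per subject, random 70/15/15
  train/validation/test division, repeated five times with derived seeds.
  The split is sample-level, so temporally overlapping windows can fall on
  both sides; this mirrors the emulated protocol and is recorded as a
  caveat.
* **LOSO plan**: for each held-out subject and each of five repetitions,
  two validation subjects are redrawn at random from the remaining
  subjects (the source protocol fixes neither the validation membership
  nor whether draws are shared across configurations; redraw-per-repetition
  is the package's choice, reproducible by seed). With 16 subjects:
  13 train / 2 validation / 1 test, 80 folds.
* **Metrics**: RMSE per fold; aggregates are the arithmetic mean and
  *sample* standard deviation (n−1; the folds are few) over subject ×
  repetition records, always recomputable from the persisted per-fold
  table. Ranking tables sort ascending by mean RMSE with ties broken by
  SD then configuration name. Bland–Altman agreement reports bias,
  SD of differences, and the 95% limits of agreement expressed as the
  half-width 1.96·SD (matching the symmetric dashed-line convention),
  optionally as percentages of an assumed 50 ml·min⁻¹·kg⁻¹ peak V̇O2.
  Every network evaluation also records the RMSE of the trivial
  mean-predictor (train-target mean) as the floor reference.

## Problem sizes used by the tests and the acceptance script

Full-size runs (16 subjects, stride 1, 100 epochs, 5 repetitions, the
60-configuration grid) are supported but are research-scale computations.
The shipped tests and `scripts/acceptance.R` run a documented desk-scale
study chosen once: 8 subjects, L = 50 windows at stride 32 (~140 windows
per subject), 30 epochs, one LOSO repetition, evaluating the best Xception
configuration and the Modified LSTM against the mean-predictor floor; plus
100–200 sessions for the synchronization property and a full 16-subject
cohort for the correlation structure. At these sizes both networks cut the
mean-predictor RMSE by clearly more than 40%.

## Numerical choices and degenerate inputs

* Truncated-normal draws use inverse-CDF sampling; zero SD degenerates to
  the (clamped) mean.
* The cross-correlation search is bounded (±120 s) and tie-broken toward
  lag 0; zero-variance inputs are an error, not a silent 0.
* Correlation coefficients of constant series are reported `NA`
  (undefined), never 0.
* Batch-norm running statistics are part of the checkpointed model state;
  evaluation always runs in inference mode.
* The depthwise convolution is implemented as a block-masked standard
  convolution (fast im2col path); the mask is re-applied to gradients so
  off-block weights stay exactly zero, and the reported parameter count is
  the free count.
* Divergent training (non-finite loss) raises a classed condition rather
  than returning garbage.

## Known limitations

The generator's kinetics are single-compartment and ignore the slow V̇O2
component, drift and temperature; its subject heterogeneity is limited to
the listed latent parameters. Correlation magnitudes printed by the real
study are data-specific and are intentionally not targets — only the sign
pattern and the Spearman-vs-Pearson gap are reproduced. Training at desk
scale shows occasional hard LOSO folds (subjects whose latent gains sit in
the distribution tails); the aggregate criterion absorbs this, as it does
in the emulated study.
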