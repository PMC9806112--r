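---
title: "Measuring upper limb use from wrist-worn IMUs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring upper limb use from wrist-worn IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbuse)
```

## The construct and the measures

Upper limb *use* is a binary construct: at any instant, is the arm engaged
in a voluntary, functionally meaningful movement or posture? Human
annotators watching video resolve this easily; an algorithm watching only a
wrist-worn IMU must infer it from linear acceleration, angular velocity and
(optionally) the magnetic field. `limbuse` implements the measure families
in use for this problem and the machinery to compare them on a common
footing. This vignette records the package's own account of the models, the
parameters that matter, and the choices made where the design was open.

### Data model

A dataset is a single tidy table, one row per 50 Hz timestamp per subject
and arm: sensor columns (`ax..az` in g, `gx..gz` in deg/s, `mx..mz`
arbitrary units), four binary annotation tracks (two annotators × two
passes, recorded at the 30 Hz video rate and upsampled by zero-order hold),
a task track and an Arm/Hand/NonFunctional movement-type track. Ground
truth is the majority vote of the four tracks with 2–2 ties labelled
non-functional — the conservative choice, since disagreement usually marks
ambiguous, borderline-functional behaviour.

Zero-order-hold resampling is used everywhere a grid must change (missing
raw samples, 30→50 Hz annotations, aligning 1–2 Hz use signals to the
evaluation grid). It never invents values — every output sample is an input
sample — which matters for binary and categorical tracks where
interpolation would be meaningless.

### Pre-processing

* **Rest detection.** A rest period is ≥ 10 s in which every gyroscope
  axis has sample variance < 0.15 (deg/s)². The threshold is read literally
  as a variance (the figure is dimensionally ambiguous in the field's
  descriptions); the record is scanned in non-overlapping 1 s blocks and
  qualifying runs are merged, an O(N) rule with no windowing free
  parameters. Both numbers are arguments.
* **Gyro offset correction.** The per-axis mean over each rest period is
  subtracted from that rest's start until the next rest begins. Samples
  before the first rest are untouched — there is no offset estimate to
  apply there, and guessing one backwards would corrupt the signal shape.
* **Median filter.** A 5-sample running median per accelerometer axis,
  shrinking at the edges; non-finite samples are dropped within each
  window, which is also the package's only handling of missing
  accelerometer data beyond zero-order hold.

### Orientation estimation

Madgwick (gradient-descent, default for the gross-movement and
vector-magnitude pipelines, 6-DOF) and Mahony (explicit complementary,
default for activity counts, 9-DOF) filters are implemented in C++ with the
published update equations. Gains default to the algorithms' published
values (β = 0.1; Kp = 1, Ki = 0.3) and are exposed. Quaternions are
Hamilton, scalar-first, body-to-earth, z-up; the filter is initialised from
the first accelerometer sample's tilt so static accuracy does not depend on
a long convergence transient.

Euler angles use the Z-Y-X (yaw-pitch-roll) convention with **pitch defined
as the elevation of the body x axis** — the forearm long axis for a
wrist-worn device — above the horizontal. A forearm flat on a table has
pitch ≈ 0°, hanging by the side ≈ −90°. Yaw is unwrapped before any
windowed range computation so a ±180° crossing cannot masquerade as a 360°
excursion. Whether a 6-DOF or 9-DOF Madgwick was appropriate for the
orientation-based measures is not settled in the source literature; the
package defaults to 6-DOF for GM/VM (yaw enters only as a within-window
range, where heading drift is irrelevant) and 9-DOF Mahony for AC.

## The four single-rule measures

| measure | rule | output rate |
|---|---|---|
| VM | counts > 0 | 1 Hz |
| AC | laterality index within ±0.95 band | 1 Hz |
| GM | Δyaw + Δpitch > 30° and \|mean pitch\| < 30° | 2 Hz |
| GMAC | counts > 0 and \|mean pitch\| < 30° | 1 Hz |

Parameter defaults: dead-band ±0.068 g, quantization step 0.017 g, angular
threshold 30°, functional pitch band ±30°, laterality threshold ±0.95 —
the values the measures were published with. All are function arguments and
YAML-configurable.

Numerical choices worth recording:

* **Zero-phase filtering.** All 0.25–2.5 Hz Butterworth band-passes run
  forward-backward (`filtfilt`); this is an offline pipeline and a causal
  filter's group delay would misalign counts with annotations. The filter
  has 4 poles (an order-2 prototype): at the very narrow normalized band
  (0.005–0.05 of Nyquist at 50 Hz) an 8-pole transfer-function band-pass is
  numerically fragile under `filtfilt`, while the 4-pole filter is stable
  and matches the stated overall order.
* **Activity-count rectification.** Band-passing the magnitude of the
  gravity-free acceleration yields a zero-mean signal, whose 1 s bin means
  would be ≈ 0 and signed; the counts would vanish and `floor()` would be
  undefined. The filtered magnitude is therefore rectified (absolute value)
  before binning, the standard resolution in activity-count
  implementations.
* **Bins and windows.** All 1 s bins are anchored at the recording's first
  timestamp; the 5 s/4 s-overlap moving average is window 5, hop 1,
  stamped at the window end, which yields exactly 1 Hz. GM windows are 2 s
  with 0.5 s hop. Δ-angles are window ranges (max − min); the pitch
  condition is evaluated on the window mean. Strict inequalities
  (`> 30°`, `counts > 0`) follow the rules' literal statements.
* **Laterality.** The index is LI = (c_dom − c_nondom)/(c_dom + c_nondom),
  the only orientation of the ratio consistent with the published threshold
  semantics (exclusively dominant movement ⇒ LI = 1 ⇒ non-dominant arm
  flagged unused, and symmetrically). Seconds where both arms have zero
  counts have an undefined index and are scored as no use on either arm.
  Instantaneous 1 Hz counts are used, unsmoothed.

## The learning protocol

Features are computed on non-overlapping 0.25 s windows of the 50 Hz
accelerometer: mean and population variance per axis, and mean, variance,
minimum, maximum and kernel-density Shannon entropy (Gaussian kernel,
bandwidth 0.2 g) of the per-sample 2-norm — 11 features. Population
variance (divide by n) is used because these are descriptive window
statistics, not estimates of a sampling distribution. The window label is
the consensus ground truth at the window centre (0.125 s from the start),
not a majority over the window. At 50 Hz a 0.25 s window alternates between
12 and 13 samples; windows are tiled by time, so a 10 s record yields
exactly 40 of them. The window length is configurable (`ml.window_s`) for
window-size sweeps.

Three classifiers are provided: a random forest (ranger), a class-weighted
RBF SVM (e1071, inverse-frequency class weights), and a three-layer MLP —
read literally as input + one hidden layer + output (`nnet`, 16 hidden
units, weight decay 1e-3); `nnet` supports exactly one hidden layer, and on
11 input features a deeper network buys nothing. Features are z-scored with
outer-training statistics for the SVM and MLP (RBF kernels are
scale-sensitive); the forest is scale-invariant and uses raw features.

Hyper-parameters (forest size ∈ {10, 50, 100, 200}; SVM C ∈ {0.1, 1, 10,
100} × γ ∈ {0.001, 0.01, 0.1, 1} — conventional log grids) are selected by
nested cross-validation: inside each outer training set, every training
fold serves as the validation fold once, and the grid point with the best
mean Youden index wins (ties to the first). The MLP architecture is fixed —
the protocol grid-searches only the forest and SVM. The intra-subject
scheme is stratified 5-fold, repeated 10 times with fresh splits; the
inter-subject scheme is leave-one-subject-out with the inner folds grouped
by training subject. Every fit records the row indices used for selection
and for testing, and the test suite asserts their disjointness — the leak
check is bookkeeping over actual indices, not convention.

Gyroscope features (per-axis mean and variance) exist behind
`gyro_features = TRUE`, default off, reflecting their reported lack of
added value.

## Evaluation

Use signals are compared against the 50 Hz consensus ground truth by
forward zero-order hold over the overlapping span; a signal stamped at bin
ends therefore carries up to one bin of alignment lag, which refinement of
the evaluation grid does not change. Sensitivity, specificity and
J = sensitivity + specificity − 1 are computed from pooled confusion
counts; measure families are compared with one-way ANOVA and pairwise
Welch t-tests (group variances differ strongly across families) under
Bonferroni correction. Performance-vs-class-share uses OLS of per-subject
sensitivity and specificity on the percentage of functional data (computed
from the consensus ground truth over the evaluated span). The task
ablation holds the stratified fold split fixed and filters the ablated
task's windows out of the training folds, the test folds, neither or both;
windows between tasks (task = "unknown") are excluded throughout.

## The synthetic generator

The generator scripts each arm as a state machine over epochs:

* **functional-arm** — base pitch uniform in ±20°, yaw oscillations of
  25–45° at 0.3–0.7 Hz (so a 2 s window sees > 30° of angular change),
  earth-frame acceleration bursts of 0.1–0.5 g in the 0.5–2 Hz band;
* **functional-hand** — forearm in the functional space but nearly still:
  2–6° yaw wiggle, intermittent 0.05–0.14 g accelerations with a ~50%
  duty cycle (writing/typing: partially sub-dead-band);
* **gait** — base pitch −80…−70° with ±10–16° pendular swing at
  0.85–1.1 Hz and matching 0.15–0.35 g accelerations;
* **rest** — static, ≥ 10 s (so rest detection and offset correction are
  always exercised), posture drawn from a tabletop/hanging mixture, held
  across consecutive rest epochs.

A greedy scheduler steers the running functional share towards the target
(default 0.45–0.7 for controls, 0.25–0.4 for patients' affected arms,
which also get movement amplitudes attenuated by 0.6); epochs are 8–18 s,
so the achievable precision is bounded by epoch granularity — the
scheduler errors out beyond max(0.1, 12 s/duration), and 10-minute records
land within ±5%. The scripted yaw/pitch profile (zero roll) *is* the
orientation ground truth: body angular rates are derived from it
analytically (ω = (ψ̇ sin θ, −θ̇, ψ̇ cos θ)), the accelerometer reads the
true specific force rotated into the body frame plus Gaussian noise
(default 0.01 g), the gyroscope adds a constant per-axis bias (default
(0.2, −0.1, 0.15) deg/s) plus noise (0.2 deg/s), and the magnetometer
reads a fixed dipping earth field. Annotator tracks are the true labels on
a 30 Hz grid with independent 2% symmetric flips per annotator-pass — a
default, not a claim about real annotators. Arms are generated
independently with role-specific shares; bimanual coupling is represented
statistically rather than by a shared schedule. A `pitch_only` mode gives
every epoch identical movement statistics so the classes differ only in
forearm pitch — the planted-signal configuration used to test the
interpretation machinery.

What the generator does **not** emulate: biomechanical detail (joint
kinematics, roll, soft-tissue artefacts), magnetic disturbance, annotator
bias that correlates with movement type, task-to-task variability in
movement statistics beyond the four epoch archetypes, and real class
overlap, which is far larger in life than here. Consequently the synthetic
cohort yields much higher absolute Youden indices (forest ≈ 0.95, GMAC
≈ 0.75, GM ≈ 0.54, AC ≈ 0.38, VM ≈ 0.20 at the default seed) than any
real study; what the tests assert is the *structure* — counting is
sensitive but unspecific, the orientation rule is specific but
insensitive, the hybrid dominates both, subject-specific learning
dominates the hybrid, mean ax tracks pitch, withheld gait collapses
specificity — not the absolute numbers.

## Problem sizes and determinism

The test suite runs the cohort-level checks on 15 subjects × 2 arms ×
180 s (50 Hz), with intra-subject cross-validation at 2 iterations × 5
folds; the share-sweep uses six single-arm records of 120 s and the
planted-signal cohort four subjects × 120 s. These sizes are the package's
choice of a desk-scale experiment: large enough that the directional
results are stable across the sampling noise at a fixed seed, small enough
to iterate on. All randomness flows from explicit integer seeds (cohort →
per-arm seeds; cross-validation → per-fit seeds), and equal seeds reproduce
results bit-for-bit, including fold assignments.

## Known limitations

* Yaw from 6-DOF fusion is only relatively meaningful; GM uses it solely
  as a within-window range, but any analysis of absolute heading would
  need the 9-DOF path.
* The use-signal alignment lag (≤ 1 bin) slightly penalises all measures
  near epoch boundaries; it affects them equally and cancels in
  comparisons.
* Inter-subject evaluation on the synthetic cohort is optimistic: subjects
  are drawn from one generative family, so leave-one-subject-out transfers
  far better than across real people.
* The annotation model (independent symmetric flips) cannot produce the
  structured inter-rater disagreement that motivates consensus labelling
  in real studies; consensus here mostly just denoises.
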