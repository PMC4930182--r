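---
title: "Methods: skeletal-motion FMA scoring and the normalized-jerk statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeletal-motion FMA scoring and the normalized-jerk statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmscore)
```

## The problem

The Fugl-Meyer Assessment (FMA) is the standard post-stroke motor impairment
scale: a therapist watches each movement item and grades it 0 (cannot
perform), 1 (partial) or 2 (full). It is reliable but requires a trained
assessor, which limits its use in home-based rehabilitation. `fmscore`
implements an automated alternative for the 13 upper-extremity motor items
that are observable from skeletal joint tracking with a consumer depth
camera: a supervised pipeline that predicts each item's 0/1/2 score from
kinematic features, and a complementary, therapist-independent smoothness
statistic (the dimensionless normalized jerk) that quantifies movement
quality directly.

The data model is one recording per item attempt: frames of 31 variables
(time plus ten joints — head, shoulder center, and both shoulders, elbows,
wrists and hands — in camera coordinates, meters) at a nominal 30 Hz. The
remaining 20 FMA items need finger/forearm-rotation tracking that a skeleton
of this granularity cannot provide and are out of scope.

## Preprocessing

Three steps make recordings from different patients, arms and sessions
commensurable:

* **Mirroring.** Right-arm recordings are reflected about the sagittal
  plane, approximated as the vertical plane through the first-frame shoulder
  center with normal along the camera x axis, with left/right labels
  swapped. No torso re-orientation is applied; subjects are assumed to face
  the camera approximately frontally. The reflection is an isometry, so all
  inter-joint distances are preserved exactly.
* **Clipping.** The rest periods before and after the movement are removed
  by thresholding the hand joint's smoothed per-frame displacement,
  expressed per body length. Defaults: threshold 0.002 (0.2 % of the summed
  arm-segment length per frame), 5-frame moving-average smoothing, 5 retained
  margin frames. All four constants are exposed because the "right" onset
  rule depends on the capture setup. Whether the displacement rule should
  watch the hand only or the maximum over joints is genuinely open; both are
  implemented (`clip_joint`), with the hand as default since the hand moves
  most in every implemented item. A recording in which nothing exceeds the
  threshold is rejected ("no motion detected"); the pipeline wrapper
  [`preprocess_recording()`] instead falls back to the whole window and
  flags it, because a zero-amplitude attempt is exactly what a score-0
  performance looks like and must still be featurized.
* **Pose normalization.** Positions are translated so the first clipped
  frame's shoulder center is the origin, then divided by the summed
  arm-segment length L = |wrist−elbow| + |elbow−shoulder| +
  |shoulder−shoulder center| of the moving arm. L is averaged over frames by
  default to damp sensor jitter (`length_mode = "first"` reproduces the
  single-frame reading; the two differ only through noise). The output is
  dimensionless and invariant to global translation and uniform scaling of
  the input — an invariance the test suite asserts end to end through the
  feature vector.

Irregular time stamps are linearly interpolated onto the nominal uniform
grid first, since everything downstream (smoothing windows, derivatives)
assumes uniform sampling.

## The normalized-jerk statistic

Jerk is the third time-derivative of position. With P(t) the 18-dimensional
vector stacking the six moving-side joints, the smoothness score is

$$NJ = \sqrt{\tfrac12 \int_{T_1}^{T_2} \lVert \ddot{\dot P}(t)\rVert^2 \, dt
  \;\times\; \mathrm{duration}^5 / \mathrm{length}^2 },$$

with duration = T2 − T1 the clipped length and length the maximum distance
of P(t) from P(T1). The duration⁵/length² factor makes the quantity
dimensionless: movements of different speeds and sizes become comparable,
and the test suite asserts invariance under random spatial scalings and time
dilations to a relative 10⁻⁶. A minimum-jerk reach — the quintic
x(t) = D(10τ³ − 15τ⁴ + 6τ⁵) with ∫jerk² dt = 720 D²/T⁵ — attains the floor
√360 ≈ 18.97, which anchors the scale; scores are reported as log₁₀ because
they are strongly right-skewed across a cohort. The base-10 choice (rather
than natural log) keeps cohort means in the low units given the ≈19 floor
and is overridable in `log_jerk()`.

Numerical choices:

* Differentiation is three repeated central differences at the frame rate,
  with no smoothing, so results are exactly reproducible; each application
  trims one sample per end, so at least 7 frames are needed.
* The trapezoidal integral over the 6-sample-shortened jerk series is
  extended to the full window [T1, T2] by holding the boundary jerk values
  constant over the trimmed samples. Without this the canonical minimum-jerk
  fixture loses ≈5 % of its integral (squared jerk is maximal at the
  endpoints of a quintic) and misses its closed form; with it the 300 Hz
  fixture agrees with √360 to better than 0.1 %.
* "length" defaults to the full 18-dimensional displacement norm; the
  hand-only reading of the movement extent is available via
  `length_joint = "hand"` since either convention is defensible.
* The ½ factor sits inside the square root, following the defining
  expression literally.
* A `motion_recording` that shows no displacement at all is rejected rather
  than scored (length → 0 makes NJ unbounded).

The flexor-synergy reach (hand toward the opposite ear; `elbow_flexion` in
the item enumeration) is the item conventionally used for cohort smoothness
comparisons, and is what `pipeline_jerk()` analyzes by default.

## Features and score prediction

Each preprocessed recording is reduced to a fixed, versioned roster of 93
features: five summaries (min, max, range, variance, mean) of 18 kinematic
series — four joint angles (elbow; shoulder to elbow and to wrist; trunk
axis to hand), eight joint distances (hand–shoulder, hand–head, elbow–head,
hand–shoulder center, wrist–head, hand–contralateral shoulder,
wrist–shoulder, elbow–shoulder center) and six per-axis hand/wrist
displacement components — plus the normalized jerk, the movement duration,
and the area of the hand path's axis-aligned bounding rectangle in the
frontal plane. Range and variance summaries matter because the attainable
range of motion grows with the score; "bounding" is implemented both as
per-series range and as the frontal-plane rectangle area since the term
admits both readings. The roster is identical for all items (the
per-item feature count could legitimately vary; a fixed roster was chosen
for reproducibility and model portability) and is version-stamped
(`FEATURE_ROSTER_VERSION`) into every trained model, which refuses
mismatched feature names at prediction time.

Scoring is deliberately conventional: per item, features are standardized,
projected onto k ∈ [4, 10] principal components (component signs fixed by a
largest-loading-positive convention so bases are deterministic), and
classified by one shared network — a single hidden layer of 16 logistic
units with a 3-way softmax, L2 penalty 10⁻³, at most 2000 iterations
(`nnet`). The small capacity suits cohorts of tens-to-hundreds of
recordings per item; the architecture is fixed across items on purpose, with
only k tunable (`select_k()` picks it by inner cross-validation, ties toward
the smaller k). Class imbalance — real cohorts are dominated by one score —
is handled by random oversampling of minority classes up to the majority
count, applied inside training folds only; the held-out fold is never
touched, and a membership test asserts the resampler can only replicate
existing rows. Evaluation uses stratified k-fold cross-validation
(k ∈ [8, 10], default 10; stratification requires every class to have at
least k members, otherwise plain random folds), with standardization and PCA
refit inside each training fold to avoid leakage. Fold accuracy is exact
agreement with the reference score; argmax ties break toward the lower
score, the conservative clinical choice.

Cohort-level validity is summarized by `evaluate_cohort()`: Pearson
correlation of the predicted 13-item sum (0–26) against the therapist
13-item sum and against the full 33-item total (0–66); a paired t-test of
log-jerk between hemiplegic and non-hemiplegic arms; and Spearman
correlation between hemiplegic log-jerk and Brunnstrom arm stage restricted
to stages 3–6 (below stage 3 the flexor-synergy movement is largely absent,
so the smoothness score is not interpretable as coordination quality).

## The synthetic cohort generator

`synth_motion()` builds one attempt: the hand follows an item-specific
straight path scaled by the achieved fraction of the item's full range of
motion, driven by the minimum-jerk profile; elbow and wrist follow by
two-link inverse kinematics with fixed segment lengths (0.28 m upper arm,
0.34 m elbow-to-hand, 0.18 m half-shoulder — plausible adult values, not
anthropometric fits); trunk joints hold still; band-limited tremor
(4–10 Hz, inside the 15 Hz Nyquist of 30 Hz sampling, synthesized as a
random sinusoid sum) is added to the arm with amplitude tapering up the
chain; white jitter is added to every joint; 0.7 s of still padding wraps
the reach. The score class sets the amplitude fraction — class 0 draws from
[0, 0.2], class 1 from [0.3, 0.7], class 2 from [0.8, 1] — so amplitude is
monotone in score by construction. `synth_cohort()` draws a per-subject
severity, maps it to a Brunnstrom stage, assigns item scores by severity
rank so that every item has exactly the requested count per class, gives the
hemiplegic arm stage-dependent tremor and the non-hemiplegic arm
full-amplitude, near-floor-tremor performance, and emits a validated score
table alongside the recordings.

Two generator scales deserve explanation. First, tremor and jitter default
to tens of micrometers (`default_stage_tremor()`: 200 µm at stage 1 down to
20 µm at stage 6; jitter 20 µm), far below the millimeter tremor of real
patients. The reason is that the smoothness statistic is computed from
*unsmoothed* third differences at 30 Hz, which amplify displacement noise by
roughly (fs/2)³ ≈ 3·10³ s⁻³; at these scales the healthy-arm log₁₀ jerk sits
just above the √360 floor (≈1.4) and hemiplegic arms span ≈1.5–2.6, i.e. the
generator's amplitudes are *effective* post-tracking-filter amplitudes
calibrated to the dimensionless-jerk scale, not physical tremor excursions.
Real sensor traces carry more noise and would be pre-filtered (a
Savitzky–Golay or low-pass step before differentiation); that filter is
deliberately not part of the deterministic default path. Second, the
generator emulates goal-directed reaches with independent additive noise: it
does not model synergy coupling between joints, occlusion dropouts,
tracking-loss artifacts, or the correlated, spiky error structure of real
depth-camera skeletons. Passing tests therefore demonstrate that the
pipeline recovers scores when amplitude and tremor actually encode them, and
that the estimators have the asserted invariances — not that real patients
are classified at any particular accuracy.

## Study sizes used in validation

The package's own validation study (`run_validation_study()`, exercised by
the test suite and `scripts/acceptance.R`) uses 13 items × 3 classes × 70
recordings per item (210 synthetic subjects, one hemiplegic recording per
item each plus a paired non-hemiplegic flexor-synergy recording), 10-fold
cross-validation, and a fixed k = 6 components; smaller examples in the
documentation use 5 per class. On this design the per-item accuracies, the
predicted-vs-generative score correlations and the cohort smoothness
contrasts are all recomputed at run time; no reported number is stored.

## Known limitations

* Occlusion is not handled: items that hide the hand from the camera (hand
  to lumbar spine) are modeled only as far as the skeleton stream reports
  positions at all.
* Forearm pronation/supination cannot be observed from this joint set; the
  two rotation items are predicted from the proximal kinematics that
  accompany them, which caps their attainable accuracy on real data.
* The clipping rule is a documented, tunable stand-in; real capture
  pipelines may need different constants per item.
* The generator's realism limits are listed above; in particular, per-item
  accuracy on synthetic data should be read as a pipeline correctness check,
  not a clinical performance claim.
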