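---
title: "Methods: posture recognition and fall monitoring from skeleton joints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture recognition and fall monitoring from skeleton joints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`skelwatch` implements a vision-based telecare/telerehabilitation pipeline
that works entirely on streams of named 3D body-joint coordinates, the output
a consumer depth sensor's skeleton tracker would produce. Everything from the
network up is built in the package; a parametric simulator replaces the
camera so the whole pipeline is testable without hardware or recordings.

## The network

The core estimator is a single-hidden-layer perceptron fit by `mlp(x, y)`.
Units compute `f(sum_i w_i x_i - theta)`: the bias enters with a negative
sign and is trained as a weight on a constant input of -1. The objective is
the un-averaged sum-form squared error

    E = 1/2 * sum_p sum_k (d_k^p - o_k^p)^2,

and training is full-batch gradient descent with the standard backpropagated
deltas: `D'_k = (d_k - o_k) f'(v'_k)` at the output and
`D_j = (sum_k D'_k w'_kj) f'(v_j)` at the hidden layer. Training stops when
`E <= max_error` or at `max_epochs`.

Two numerical choices matter:

* **Step scaling.** The summed batch step grows linearly with the training
  set, so at the default learning rate of 0.3 a 600-pattern set takes steps
  two orders of magnitude too large: the sigmoids saturate on the first few
  epochs and the network stays at chance. We therefore divide the summed
  gradient by the number of patterns (`batch_scale = "mean"`); the raw summed
  step stays available as `batch_scale = "sum"` for small sets. The objective
  itself (and the `max_error` stop rule) remains on the sum scale; as a
  consequence `converged = TRUE` is rare at realistic set sizes -- an error
  sum of 0.01 over 3000 output terms demands per-output residuals of ~0.002
  -- and the epoch cap is the effective stopping rule. `mlp_mse(...,
  per_pattern = TRUE)` reports the averaged error for human consumption.
* **Transfer functions.** The default is the logistic sigmoid. The `tanh`
  option uses tanh hidden units and a tanh output affinely rescaled onto
  (0, 1); without the rescale the 0/1 one-hot targets would be unreachable
  and the two transfer functions could not be compared on the same targets.

Weights initialize uniformly in `[-0.5, 0.5]` from an explicit seed; training
is bit-reproducible given the seed and configuration. The analytic gradients
are verified against central finite differences to 1e-6 in the test suite.

The hidden-layer sizing heuristic `size_hidden(n_in, n_out)` returns
`round(((n_in + n_out)/3)*2)`. For the posture networks this yields 13 for
both body halves; the builders default instead to the empirically recommended
12 (upper) and 10 (lower) hidden units, and both values are overridable.

## Features

`extract_features()` makes classification independent of where the subject
stands and how tall they are:

1. translate to a body-anchored origin -- the shoulder midpoint for
   upper-body joint sets, the hip midpoint for lower-body sets;
2. divide by the calibrated subject height (head-minus-feet from a standing
   frame, `estimate_height()`);
3. map `[-1, 1]` affinely onto `[0, 1]` and clip, so features sit in the
   sigmoid's input range.

The upper-body joint set is `{shoulder midpoint, elbows, hands}` -- 15
coordinates; the shoulders themselves contribute through the anchor. A
six-joint, 18-input variant (`upper_joint_set18()`) lists both shoulders
explicitly. The lower set is `{hips, knees, feet}`, 18 coordinates.

Fall detection consumes a sliding window of 10 consecutive head positions
(a third of a second at 30 Hz): a single static head position cannot express
an abrupt movement, and the window is the smallest temporal context that
can. Within a window the vertical origin is the calibrated *standing head
level* and the horizontal origin is the head position in the oldest frame,
so windows remain translation invariant while preserving absolute descent
depth. Calibration is an enrollment step: it is taken once, with the camera
level with the subject, and reused; this is what makes steep vertical camera
angles degrade detection (the observed descent no longer matches the
enrolled geometry).

`ratio_posture()` keeps the simple pre-network baseline: standing keeps the
head-to-knee vertical distance at or above two thirds of the height, sitting
roughly halves it. The boundary case is assigned to standing, a documented
deterministic tie-break.

## The alarm state machine

A fall observation in `Normal` starts the episode timer and moves to
`Abnormal`. Standing up while `Abnormal` or `Urgent` discards the episode.
Staying down longer than `safety_time` (default 10 s) escalates to `Urgent`;
`urgent_grace` (default 5 s) later the alarm fires and the stage latches at
`Emergency`, which ignores every observation until `manual_reset()` -- only
an authorized manual action clears a fired alarm. Frames in which the head
is out of view leave the timer running; continuous fall observations do not
restart it (one timer per episode). "Standing up" is debounced: the
lower-body classifier must report standing *and* the head must have
recovered to within 20% of its standing level, sustained for half a second.
Neither grace period is prescribed anywhere; 10 s + 5 s are the package's
defaults. The alarm action is a pluggable hook (`on_alarm`); delivery beyond
the structured event log is out of scope.

A rehabilitation session (`run_rehab_session()`) walks an ordered posture
plan; an *attempt* is a 2 s evaluation window that succeeds when at least
70% of its frames classify as the target. The attempt definition is ours --
the session protocol only counts discrete tries.

## The simulator

The synthetic module replaces both the camera and the recorded subjects.
Subjects are parameterized by height (default pool: six subjects evenly
spaced over 1.50-1.95 m) with fixed anthropometric segment ratios (shoulders
at 0.818 of height, hips 0.53, knees 0.285, ankles 0.039, arm segments 0.19
and 0.21). Posture templates are arm-elevation/leg configurations: arms
hanging at 10 degrees, outstretched at 90, raised at 125 (hand just above
the head -- a raise that also fits a 45-degree vertical field of view at
2.5 m for the tallest subject); sitting drops the pelvis to 0.30 of height
with knees forward, which respects the 2:3 standing head-knee geometry and
roughly halves it when seated.

The camera applies subject yaw, a vertical-angle rig (the camera rises and
pitches down about an aim point at mount height), a rectangular 58 x 45
degree frustum that marks out-of-view joints undetected, and additive
Gaussian jitter whose sigma grows beyond 4.5 m depth
(`noise_sigma0 * (1 + 0.08 * max(0, z - 4.5))`). The default mount height is
1.05 m for dataset/rehab cameras (full-body visibility at 2.5 m) and 0.7 m
for fall-watch cameras (the on-ground head stays in frame from about 1 m
outward). These mounts were chosen from the frustum geometry, not fitted to
any result.

Falls interpolate the skeleton (cosine easing) from standing to a *crumpled*
lying pose over 0.5-1.0 s: the head ends at 0.2 of the subject height above
the ground and about 0.3 of the height away from the feet, in a uniformly
random direction. A rigid full-length topple would carry the head ~1.5 m
sideways and out of any near-field frustum, making mid-range detection
geometrically impossible; real falls fold. Confounders are a quick sit
(0.8 s descent to the sitting template) and bending down (head to ~55% of
height, then recovery).

Training sets are stratified (class counts differ by at most one), shuffled,
rendered across the subject pool, and written to a plain-text dataset format
(six decimals, label last). Distractor frames for rejection testing are
*intermediate* configurations matching no trained class: arm elevations
between the templates (at least 20 degrees from every template combination
-- poses closer than that are natural variation of a class, not negatives)
and partial crouches between standing and sitting, all additionally at least
3 pose-jitter sigmas from every template in joint space.

## Evaluation conventions

A *trial* is one rendered situation (a posture hold or one scripted event),
not one frame. True positives are counted over the positive trials and true
negatives over the negative trials, so FP = 100 - TP and FN = 100 - TN by
construction; `confusion_rates()` enforces this convention. All sweeps
(`sweep_hidden()`, `sweep_instances()`, `sweep_distance()`,
`sweep_angles()`) regenerate data, retrain and re-evaluate per level and
seed, and are deterministic given their seeds.

Default study sizes: 632 upper / 735 lower training instances, 500 held-out
positives and 500 distractors per body half, five seeds; the fall studies
train on 600 fall and 600 non-fall windows and run 100 scripted sequences
per condition and seed with 20 s on the ground. The state-machine timing
(10 s + 5 s) means an alarm fires about 15 s into a fall, well inside the
20 s window. The test suite exercises the same studies at these sizes; unit
tests use smaller nets and sets.

## What passing tests do and do not show

The simulator reproduces the pipeline's *mechanisms*: translation/scale
invariance of features, frustum dropout below 1 m, degradation at steep
vertical angles (the enrolled vertical geometry no longer matches), and
insensitivity to horizontal rotation and subject stature. It does not
emulate real skeleton-tracker failure modes (occlusion, limb swaps,
tracking latency), natural postural variability beyond isotropic jitter, or
depth-dependent artifacts beyond a noise ramp. Two known consequences:

* **Capacity effects vanish.** On cleanly separable synthetic clusters every
  hidden-layer size from 8/6 to 16/14 reaches the same test accuracy, so the
  hidden-neuron sweep shows a plateau whose maximum the recommended 12/10
  configuration attains, rather than a unimodal peak; degradation at the
  extremes is a property of noisy real recordings.
* **Threshold rejection of unseen poses fails.** A closed-set MLP trained to
  saturation partitions the entire input space confidently: measured along
  the arm-elevation axis, the top output stays at 0.65-0.95 even exactly on
  inter-class boundaries, so the decoding rule (threshold 0.5, margin 0.05)
  returns `none` almost nowhere and intermediate-pose distractors are
  rejected at only ~5-10%. The corresponding acceptance check is left
  failing by design rather than weakened; genuinely high rejection rates
  would need an explicit reject class, calibrated confidences, or an
  open-set method, all outside this package's scope.

## Degenerate inputs and tie-breaks

Empty streams yield empty event lists; an empty rehabilitation plan, an
empty training set, a missing posture class, and rate computations without
both trial pools all raise typed errors. Exact arg-max ties decode to the
lowest output index when the margin is zero and to `none` otherwise. Time
running backwards in the monitor is a hard error. Non-finite training error
raises a training-diverged error rather than returning a corrupt fit.
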