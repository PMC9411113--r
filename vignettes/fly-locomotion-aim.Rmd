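---
title: "Quantifying fly locomotion and AIM scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fly locomotion and AIM scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyaim)
```

# Scope

`flyaim` quantifies open-field locomotion of a single walking fly from
per-frame tracker output — position of the body centroid and body
orientation — and scores abnormal involuntary movements (AIMs), the
dyskinesia-like abrupt accelerations that appear under chronic levodopa
exposure. The package covers measurement only: video tracking is upstream
(e.g. Ctrax), and group inference beyond means ± SEM, percent change, and a
permutation dose-trend test is delegated to standard routines
(`group_anova()` wraps `stats::aov` + `TukeyHSD`).

# Input model and conventions

A trajectory is a complete sequence of frames `0, 1, 2, ...` with finite
x/y positions and a body heading per frame. One convention is used
everywhere:

* positions are stored in **mm**; pixel input is converted on load via the
  calibration's `pixels_per_mm` and the provenance recorded in
  `source_units`;
* orientations are **degrees wrapped to [−180°, 180°)** at load;
* frame rate defaults to **30.06 frames/s**, so a 5-minute recording has
  9018 frames of 0.033 s each.

Validation is strict and nothing is repaired silently: a gap, duplicate, or
non-numeric cell aborts the load naming the first offending frame or row.
Tracker exports do go wrong (dropped frames, identity glitches), and a
quietly "fixed" trajectory would corrupt every downstream metric — the
freezing fraction in particular, since a dropped frame masquerades as a
double-length step.

# Per-frame kinematics

Differencing the trajectory gives, per frame step *i* (of *n* − 1):

* displacement `d_i` — Euclidean distance between consecutive positions
  (mm). Equivalently, the increment of cumulative traveled distance: the
  instantaneous speed is `v_i = D_{i+1} − D_i` where `D` is distance
  traveled so far;
* instantaneous speed `v_i = d_i × frame_rate` (mm/s), so values are
  frame-rate independent;
* yaw — signed heading change, wrapped to [−180°, 180°).

Three locomotor parameters summarize a recording:

* **mean speed** (mm/s): mean of `v_i`;
* **yawing** (deg/frame): mean |yaw|. The aggregation is a package
  decision — published figures plot "yawing" without units — so the
  per-step sum and a per-second rate are exposed as alternatives
  (`yawing_metric(aggregate=)`), and only monotone comparisons across
  groups should be read into the absolute value;
* **freezing fraction**: share of steps with `d_i ≤ ε`. Real centroid
  tracks never repeat a position exactly, so the literal `d = 0` rule is
  useless on data with jitter; the default tolerance is ε = 0.05 mm
  (about half a pixel at typical magnification), configurable, and ε = 0
  reproduces the literal definition on noiseless input.

All three are invariant under rigid translation/rotation of the arena;
mean speed scales linearly under uniform spatial scaling while freezing at
ε = 0 is scale-free. These invariances are enforced as property tests.

# The AIM score

The AIM score detects frames whose speed is abruptly out of line with its
local context. With a centred sliding window of `s` frames (default 21,
i.e. 10 frames ≈ ⅓ s either side), the local mean speed at step *i* is

$$ v_s(i) = \frac{1}{s} \sum_{j=i-(s-1)/2}^{i+(s-1)/2} v_j , $$

and the raw score is

$$ H = \sum_i \mathbf{1}\left\{ \left| \log_{10} \frac{v_i}{v_s(i)} \right| > c \right\}, \qquad c = 0.4 \text{ by default}. $$

Numerical and edge-case choices, each of which materially affects scores:

* **Odd windows only.** A centred window of `s` frames covers
  (s−1)/2 frames either side of the scored frame; splitting the window
  into the "before" and "from-here-on" halves covers exactly `s` frames
  only when `s` is odd, so odd `s` is enforced.
* **No shrinking edge windows.** The first and last (s−1)/2 steps are
  unscored rather than scored against a truncated window, so `H` is
  comparable across equal-length recordings; `aim_params()` records the
  expected recording length (9018) for diagnostics.
* **Absolute value.** `|log10(v_i/v_s)| > c` scores abrupt decelerations
  as well as accelerations. A one-sided variant
  (`aim_score(mode = "signed")`) is provided for sensitivity analysis.
* **Zero-speed guard.** `log10` is undefined at zero, so steps where
  `v_i` or `v_s` falls at/below `epsilon_speed` (default 1e-9 mm/s) are
  *skipped*, not clamped: stationary behavior is already captured by the
  freezing fraction, and clamping would let freeze-adjacent frames score
  spuriously large ratios in either direction. Skipped counts are
  reported; a fully stationary recording returns `H = 0` with an
  `all_skipped` flag and a warning instead of an error, so degenerate
  flies flow through cohort summaries.
* **Normalization.** Raw scores are normalized by subtracting the mean raw
  score of the *same-batch* control group (`normalize_aim()`,
  `add_normalized_aim()`), never a global constant, making the control
  mean exactly 0. Note that walking frames adjacent to long freezing bouts
  depress `v_s` and can qualify; this baseline component is shared by
  control and treated flies and is exactly what the control normalization
  removes.
* **Threshold provenance.** The default `c = 0.4` is taken as given. For
  users re-deriving a threshold from their own wild-type recordings,
  `threshold_from_controls()` pools `|log10(v_i/v_s)|` over control flies
  and returns an upper quantile (default 0.999); this is this package's
  own documented convention, not a reconstruction of how any previous
  threshold was calibrated.

`peak_deviation()` reports the maximal percent deviation
`max (v_i − v_s)/v_s × 100` over scored frames — the "largest spike"
summary often quoted alongside AIM scores.

# The synthetic-trajectory generator

No public single-fly tracking data accompany the dyskinesia assays this
package targets, so the simulator is a first-class module: it generates
trajectories with the statistical structure the analysis assumes, giving
every pipeline stage a ground truth. Each frame step is in one of three
hidden states:

* **WALK** — correlated random walk: heading diffuses by
  `Normal(0, turn_sd_deg)`; step length is `walk_speed/frame_rate` times
  lognormal noise with mean 1 and coefficient of variation
  `speed_noise_cv`;
* **FREEZE** — zero displacement, heading held. Enter/exit probabilities
  give geometric dwell times, so the walk/freeze chain has the closed-form
  stationary occupancy `enter/(enter + exit)` used by the
  parameter-recovery tests; the chain starts from this distribution;
* **BURST** — a single-frame multiplicative speed spike (`burst_gain`)
  with a ±`burst_turn_deg` heading kick, superimposed on walk steps as a
  per-frame Bernoulli event. Bursts encode the empirical signature of
  dyskinetic movement — abrupt acceleration coinciding with a large
  direction change — and are the intended AIM-qualifying events, giving a
  detection target with known positions.

Positions reflect off a circular arena wall (radial mirror; the heading
follows the realized step). Reflections shorten the occasional step, so
measured mean speed sits marginally (≪1% under defaults) below the
closed-form expectation `walk_speed × (1 − occupancy) ×
(1 + p_burst × (gain − 1))` exposed by `effective_parameters()`.

**Defaults** (the simulated "study conditions", chosen once as plausible
for a young male fly in a ~9 cm arena): 9018 frames at 30.06 frames/s,
walk speed 8 mm/s, speed-noise CV 0.3, freeze enter/exit 0.01/0.15
(occupancy 1/16), turn SD 8 deg/frame, burst rate 0.2/min, burst gain 6,
burst turn 90°, arena radius 44 mm.

**Dose.** A scalar `dose` ∈ [0, 1] stands in for levodopa concentration or
diet duration and maps linearly onto four effects: walk speed × (1 − 0.5·dose),
freeze entry × (1 + 3·dose), turn SD × (1 + 2.5·dose), burst rate
+ 20·dose per minute. At dose 1 this yields roughly −55% mean speed,
+237% freeze occupancy, and ~3× yawing relative to dose 0 — the magnitude
regime reported for strongly dosed flies — while keeping every response
monotone in dose, which is the property the tests assert.

**Reproducibility.** One master seed; cohort members get seeds by
counter-based splitting on (master, fly index, dose index), so cohorts are
reproducible and order-independent. The simulator restores the caller's
RNG stream. Hidden states are attached to each trajectory for ground-truth
tests.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: centroid measurement noise (freezes are exactly
zero displacement, so recovery tests with ε = 0 are cleaner than any real
track), tracker artifacts (identity swaps, lost frames, 180° body-axis
flips), wall-following and thigmotaxis, within-recording nonstationarity,
and temporal clustering of bursts (real dyskinesia may be diphasic;
bursts here are homogeneous Bernoulli because no temporal statistics were
available to emulate). Parameter-recovery and dose-monotonicity results on
simulated cohorts validate the *estimators*, not any biological claim.

# Cohort analysis

`summarize_fly()` composes the metrics into one row per fly;
`summarize_group()` reports n, mean, SEM = sd/√n, and percent change of
each group mean versus the control mean ((mean − control)/control × 100;
exactly 0 for the control group). Single-fly groups report SEM = 0 with an
explicit `sem_degenerate` flag rather than erroring, so toy fixtures run
end-to-end. `dose_trend()` tests monotone dose response by Spearman rank
correlation with a seeded label-permutation null (default 999
permutations, two-sided on |rho|); rank correlation is used because the
expected responses are monotone but not assumed linear, and the
permutation null avoids distributional assumptions at small n.

# Problem sizes used in the checks

The packaged checks run full-length 9018-frame recordings where the claim
concerns the study conditions: parameter recovery averages 20 seeds;
dose monotonicity uses 5 dose levels × 10 flies. Oracle-equivalence and
scale-invariance properties run on 100 random series each of 40–250
steps, where window edge effects are proportionally largest. Scenario
tests (acute rescue) use 1-minute recordings and 5 flies per arm, enough
for their directional assertions.

# Known limitations

* Body orientation is taken as a resolved directed heading; trackers that
  leave the head/tail ambiguity unresolved will inflate yawing by spurious
  ~180° flips.
* The yawing aggregation and the freezing tolerance are conventions
  (documented above); compare absolute values across studies only with
  matched settings.
* Whether historically reported AIM analyses scored or excluded
  zero-speed frames is not documented anywhere we know of; this package
  excludes them and reports the count, so the choice is auditable.
* `dose_trend()` treats flies as exchangeable under the null; batch
  structure, if any, is the user's responsibility.
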