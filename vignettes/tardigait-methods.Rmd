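---
title: "Methods: quantifying octopedal gait with tardigait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying octopedal gait with tardigait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(tardigait)
```

## The measurement model

`tardigait` analyzes planar walking of a single eight-legged animal
filmed from below on a stationary bright background, nominally at 33
frames/s. Two data streams enter the analysis:

1. a **centroid track** — per-frame body position, plus blob area and
   principal-axis length/width when the track comes from images;
2. a **leg event table** — for each leg (`L1..L4`, `R1..R4`, segment 1
   anteriormost), the alternating sequence of swing onsets (claw
   release) and stance onsets (claw touch-down), in seconds.

All downstream quantities are deterministic functions of these inputs
and the configuration in `run_config()`. Legs of segments 1–3 ("lateral
legs") are analyzed separately from the anatomically specialized fourth
pair throughout, because rear legs differ in musculature, orientation
and duty factor while sharing the step period of the lateral legs.

### Tracking and event calling

The body is segmented per frame as the largest dark blob under a
background model (default: the per-pixel median of the clip, which
assumes the background is stationary and the body traverses
substantially more than its own length during the clip; an explicit
background can be supplied when it does not). Body length and width are
the principal-axis diameters of the blob's pixel distribution
(`4*sqrt(eigenvalue)`, exact for a filled ellipse up to pixelation).

Motion metrics use a sliding window of `window_s` = 0.3 s that advances
one frame at a time, so every frame carries a state label. The window
is rounded to an integer number of frames (10 at 33 fps, i.e. 0.303 s);
speeds divide by the actual window duration. Heading follows image
conventions — 0° up-screen, increasing clockwise, wrapped differences in
(−180°, 180°].

A **stop** is any maximal run of windows with displacement ≤ 0.03 body
lengths (inclusive); a **turn**, a run of windows whose heading changed
by ≥ 28° (inclusive). Both thresholds are behaviorally calibrated
values for tardigrade-scale locomotion and are configuration keys, not
constants. Three numerical choices deserve note:

- *Stops take precedence* when a window satisfies both rules, because
  heading is numerically meaningless at near-zero displacement.
- An event spans from its first qualifying window's start to its last
  qualifying window's start plus one window length. Event boundaries
  are therefore resolved to about one window; a stop bounded by walking
  at speed v extends past the truly stationary interval by up to
  `0.03/v + window_s` seconds, which is the correct reading of a
  windowed displacement rule.
- Threshold comparisons use a 1e-9 absolute guard so that analytically
  exact boundary cases (a heading step of exactly 28°) are classified
  inclusively rather than at the mercy of floating-point rounding.

Sustained walking bouts are maximal event-free intervals of at least
`min_bout_s` = 3 s, returned ranked by duration. BL normalization uses
the clip-mean body length; at 33 fps the mean is a robust summary and
insulates the normalization from single-frame segmentation noise.

### Stride kinematics

A stride runs from stance onset to the next stance onset of the same
leg; the intervening swing onset splits it into stance and swing, with
duty factor = stance/period. Strides must lie fully inside a bout;
a stride is assigned to the bout containing its start, a deterministic
rule needed because bouts are disjoint but strides can straddle their
edges. Stride geometry (length, speed, direction change) interpolates
the track at the two stance-onset times; direction change uses the
windowed heading *at* those times rather than an average over the
stride, matching the notion of direction change per stride. Within-
animal dispersion is always the sample (n−1) standard deviation, since
per-animal stride counts are small.

### Phase offsets and the reference-cycle convention

The ipsilateral offset ϕ_I of a leg pair is measured per reference
cycle: for each interval between consecutive *swing onsets* of the
posterior (reference) leg, the first swing onset of the anterior
neighbor inside that interval, as a fraction of the interval. ϕ_C is
the same construction with the left leg of a segment as reference and
the right as partner. Cycles without a partner onset are skipped but
cycle order is preserved for successor analyses.

Anchoring the cycle at the swing onset (rather than the stance onset)
is the only convention under which the textbook geometry holds: with
duty 2/3, ϕ_I = 1/3 produces a canonical tetrapod with an anterograde
swing wave and a normalized metachronal lag of exactly 2·ϕ_I. The
package treats the in-cycle window `[onset, next onset)` as the search
window; a nearest-onset variant was considered and rejected because it
double-counts partner onsets near cycle boundaries.

### Coordination patterns and scores

Each frame's interleg coordination pattern (ICP) is a pure function of
the swinging-leg set. Frames at exactly an onset time take the *new*
state (closed-left convention), so the frame-sampled swing matrix is
the interval-membership test of the event timeline. Frames before a
leg's first event have unknown state and are excluded from composition
denominators; compositions therefore always sum to 1 over known
frames. Sets of four or more swinging lateral legs are kept as an
explicit `many` category rather than folded into `tripod_other`, so
that compositions remain a complete partition.

**CCS** pools, over the six lateral legs, the number of strides
containing the leg's most prevalent canonical (diagonal) co-swing
partner, divided by the total stride count. Partner ties break to the
lower segment, then L before R — deterministic and order-independent.
**CSS** is computed per pattern bout (maximal interval of full-set
co-swing) as overlap time over the span from the participating swings'
first onset to their last stance onset; the per-animal score is the
mean over bouts, and an animal with no bouts of a pattern has a
*missing* score, never zero. Both scores are invariant to time shifts
and uniform time rescaling, which the test suite checks explicitly.

**Metachronal lag** scans, per third-leg swing onset, the ordered
first-leg onsets until one has exactly one intervening second-leg
onset; once two intervening onsets accumulate no later candidate can
qualify and the cycle is skipped. Left and right cycles are matched by
nearest third-leg onset time (each right cycle used at most once,
within 0.75 reference periods) to form per-cycle log₂(L/R) ratios; the
mean absolute ratio converts to a percent asymmetry as (2^x − 1)·100.

### Speed partitions and group comparison

Stride speeds partition at 0.23 and 0.35 BL/s — boundaries placed at
discontinuities of the empirical speed distribution — with boundary
values assigned to the middle class ("between" read as closed). Frames
inherit the partition of the reference-leg stride containing them.

The comparison layer runs, per parameter, Shapiro–Wilk on both groups
(α = 0.05) and Levene's test; a t test is used only when *both* groups
pass normality (pooled variance if Levene's p ≥ 0.05, Welch otherwise),
else Mann–Whitney. The both-groups rule and α are conventional,
conservative choices; the tests themselves are the stock R/car
implementations. Raw p values are corrected by Benjamini–Yekutieli,
whose harmonic-sum factor (3.6454 at m = 21) makes it valid under
arbitrary dependence between the panel's parameters — appropriate here
because kinematic parameters are strongly intercorrelated. Compositional
parameters are CLR-transformed first; zeros are replaced by half the
smallest nonzero component (configurable, and reported via an
attribute), a pseudocount choice that leaves component rankings intact
across a wide range of values. The default 21-parameter panel favors
independent measurements (duty factor in, stance duration out; both
absolute and normalized speed in by design) and is an editable
character vector, not a hard-coded contract.

## The synthetic walker

`walker_spec()` fully parameterizes a ground-truthed walker: per-leg
periods and duty factors, target ϕ_I/ϕ_C (lateral chain anchored at
L3, rear pair with its own duty, period and contralateral offset),
Gaussian onset jitter, and a piecewise-constant speed/heading path.
Defaults describe a typical steady adult: 0.9 s period, lateral duty
2/3, rear duty 0.55, ϕ_I = 1/3, ϕ_C = 1/2, 250 µm body length,
0.23 BL/s. Jitter is applied to every onset and rejection-resampled
per leg so the swing/stance alternation grammar is never violated;
jitter with 4·sd exceeding the shortest phase is rejected outright
with an informative error. Rasterization renders an oriented dark
ellipse on a bright noisy background for end-to-end tests of the
segmentation stage.

The generator emulates: phase-locked stepping with realistic jitter,
stops, turns, speed changes, and the lateral/rear kinematic split. It
deliberately does **not** emulate substrate mechanics, claw grip,
footfall geometry, body deformation during turns, partial occlusions,
or illumination drift. Passing the round-trip tests therefore
demonstrates correctness of the *estimators* under the stated
measurement model, not robustness to every artifact of real video;
the tracking stage's robustness margin on real data comes from the
median background model and the clip-mean BL normalization, both of
which degrade gracefully rather than silently.

## Problem sizes and tolerances in the test suite

The suite validates noiseless round-trips to 1e-9 (event-based
quantities) or one frame (frame-sampled quantities), and uses: 10 s
walkers at 33 fps; 20 random path parameterizations against an
independently coded windowed-rule oracle; 20 jitter seeds for
parameter recovery (duty and period within 0.02, phases within 0.03);
an exhaustive 64 × 4 truth table for ICP classification; dense-grid
and brute-force interval oracles for CCS/CSS; and 500 + 200
replicates of a 21-parameter, n = 30 per group simulation verifying
>95% detection of a 3-SD shift with realized false discovery below
5%. These sizes keep the full suite under a few minutes while leaving
the Monte-Carlo assertions' error bars well inside the tested margins.

## Known limitations

- Event tables are taken as ground truth; the package validates their
  grammar but cannot recover from mislabeled onsets.
- Heading (and therefore turn calling) is undefined during stops; turns
  entirely contained in a stationary interval are attributed to the
  stop, by design.
- The CSS bout denominator uses the participating swings only; a
  pattern interrupted and resumed within the same strides counts as two
  bouts.
- The swing-partner matrix normalizes off-diagonal entries by the
  reference leg's swinging frames (the diagonal by all frames); an
  all-frames off-diagonal variant would scale rows by each leg's swing
  fraction and is easy to derive from the returned matrix if needed.
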