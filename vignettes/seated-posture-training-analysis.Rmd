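---
title: "Outcome measures and statistics for robot-assisted seated posture training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome measures and statistics for robot-assisted seated posture training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starsit)
```

## The study design this package analyzes

`starsit` implements the outcome-measure and statistics pipeline of a
three-arm seated posture training study in which healthy adults train
multidirectional reaching while supported by a trunk-assisting cable robot.
The arms differ only in how reaching targets are presented: physical markers
(PR), holographic targets through an optical see-through headset (AR), or a
fully virtual scene (VR). Each subject performs a postural star sitting test
(PSST) — one maximal seated reach in each of eight principal directions (F,
FD, D, BD, B, BND, ND, FND at 45° increments) — before and after a training
block of 12 rounds × 8 bouts (96 reaches) against targets placed at three
difficulty levels. Motion capture records fingertip and trunk center-of-mass
(COM) trajectories at 100 Hz; a seat pressure mat records the center of
pressure (COP) at 56 Hz; five 7-point Likert instruments (SSQ, ITQ, PQ, GEQ,
UEQ) probe sickness, immersive tendency, presence, engagement and enjoyment.

Because no recordings are distributed with the study, the package pairs the
analysis code with a seeded synthetic-cohort generator that emulates the
design. Every downstream stage — preprocessing, reach and workspace
geometry, COP posturography, questionnaire scoring, and the ANOVA layer — is
therefore testable end to end, and programmed effects can be recovered as
parameter-recovery properties.

## Outcome measures

**Functional reach test score (FRTS).** The distance between the start
position and the farthest fingertip position of a directional reach,
`frts()`. "Farthest" is the maximum Euclidean distance over samples (ties:
earliest sample); a projection variant (signed distance along the direction
unit vector) is available via `mode = "projection"` for sensitivity
analysis. Targets for training are placed from the baseline FRTS: basic at
100%, medium at 110%, hard at 120% of the per-direction score
(`place_targets()`).

**Sitting workspace area.** The eight farthest COM points over the
directions (`farthest_points()`) are connected in counterclockwise angular
order about their centroid (`star_polygon()`), and the polygon's shoelace
area (`polygon_area()`) measures dynamic sitting balance. The polygon is
deliberately the star polygon over exactly the eight points, not their
convex hull, mirroring how the stability limits are connected; it may be
non-convex.

**COP posturography.** After filtering, `total_excursion()` (path length,
m), `mean_velocity()` (cm/s), and approximate entropy. `approximate_entropy()`
is the classic Pincus statistic with self-matches: ApEn = Φ_m(r) − Φ_{m+1}(r),
with Φ_m the mean log fraction of embedding vectors within Chebyshev
distance r. Defaults m = 2, r = 0.2·SD (the field convention; the study does
not report its parameters). The planar series is reduced to the centered
resultant displacement √(x̃² + ỹ²) by default; a per-axis-mean mode is kept
for sensitivity analysis. ApEn conventionally lies in 0–2, but small
absolute tolerances on wide-band signals can legitimately exceed 2; such
values are flagged with a warning and only clipped on request
(`clip = TRUE`), never silently. Note also that ApEn as a function of r is
unimodal (match counts saturate at small r), so monotonicity in r should
only be expected on the coarse-tolerance branch.

**High-intense-activity rate (HIAR).** The baseline reaching workspace is
the convex hull of *all* baseline fingertip samples (`convex_hull()`;
"encompasses all trajectory points" is read as the minimal convex polygon —
an alpha-shape would add a free parameter). HIAR is the fraction of training
time the fingertip spends outside that hull: each sample after the first
contributes its preceding inter-sample interval when classified outside
(`point_in_polygon()`, ray casting; points within 1e-9 m of an edge count as
inside), divided by the trajectory time span. No sub-sample
boundary-crossing interpolation is attempted: at 100 Hz the attribution bias
is below 10 ms per crossing.

**Reach task score.** Basic/medium/hard targets score 1/2/3; a bout that
undershoots the basic target scores 0 (the study describes only levels 1–3,
but synthetic cohorts can undershoot). The cumulative score over the 96
bouts lies in [0, 288]. In the pipeline, bout levels are *re-measured* from
the data: targets are placed from the measured baseline FRTS and each bout's
measured reach distance is classified against them, rather than trusting
generator-side truth.

**Questionnaires.** Every instrument is scored by the study's uniform
normalization: the sheet sum divided by the maximum possible score
(7 × items). With items anchored 1..7 the attainable floor is 1/7, not 0 —
the package documents this rather than re-anchoring. Standard SSQ subscale
weights are deliberately not applied. The objective immersion score is an
externally supplied rubric total normalized by its maximum (`normalize_immersion()`),
with the PR arm fixed at 0 on the reality–virtuality continuum.

## Preprocessing

Trajectories and COP series are validated (strictly increasing timestamps;
non-finite runs up to 0.1 s — about ten motion-capture samples — repaired by
linear interpolation, longer gaps rejected with the offending interval
named) and lowpass filtered with a fourth-order Butterworth filter at 10 Hz
(motion capture) and 6 Hz (COP). Filtering is applied forward and backward:
the study does not state zero-phase filtering, but any phase lag would bias
the timing of farthest-reach samples, so the dual pass is used and its
consequence documented — the effective magnitude response is squared,
attenuating the nominal cutoff to −6 dB (amplitude 0.5). Because plain
forward–backward filtering starts from zero state, the implementation pads
each end with 512 samples of odd-reflected signal and discards them after
filtering, keeping edge transients out of the series (DC is preserved to
1e-9). Whole-phase series are filtered before segmentation into bouts.

## The statistics layer

For each pre/post measure the package runs a split-plot (mixed
between-within) ANOVA with arm (PR/AR/VR) as the between-subjects factor and
test time (T0/T1) as the within-subjects factor: the between stratum tests
the arm effect against subjects-within-arms error; the within stratum tests
time and the arm × time interaction against the subject × time residual.
With only two within levels sphericity holds trivially, so no
Greenhouse–Geisser correction is applied. Partial η² uses each effect's own
error term, SS_effect / (SS_effect + SS_error). Time-invariant measures
(HIAR, reach task score, ITQ/PQ/GEQ/UEQ) get one-way between-arms ANOVAs;
the presence questionnaire compares AR and VR only (the PR arm has no
virtual environment to be present in and is defined as zero). Homoscedasticity
is checked with Levene's test (center = mean; Brown–Forsythe via
`center = "median"`), normality with Shapiro–Wilk plus Q-Q coordinates, at
α = 0.05 throughout.

Post-hoc pairwise arm comparisons use pooled-variance t tests with
Bonferroni correction over the k = 3 pairs (the study does not state k;
three arms give three contrasts), run on T1 − T0 change scores for the
mixed designs, and are gated on a significant omnibus effect. Within-arm
pre/post comparisons are paired t tests. An exact-null effect (effect SS
identically zero) is reported as F = 0, p = 1 rather than the 0/0
indeterminate.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the study
conditions: 21 subjects per arm, three arms, 8 directions, 12 × 8 training
bouts with shuffled direction order per round. Where the study prints
numbers, the defaults encode them; where it prints nothing, a single
realistic choice was made and is listed here.

- **Reach kinematics** (unreported): minimum-jerk out-and-back fingertip
  displacement along the direction unit vector, peak = trial amplitude —
  smooth, parameter-light, standard for point-to-point movements. Marker
  noise is i.i.d. Gaussian, SD 5 mm. The COM trajectory is a scaled copy of
  the fingertip displacement (ratio 0.35): the study estimates COM from a
  29-marker anthropometric model that is out of scope here, so the
  generator emits COM directly.
- **Amplitudes** (unreported): baseline FRTS 0.25 ± 0.03 m per subject with
  0.02 m per-direction spread — plausible seated reach excursions.
  Pre→post multiplicative gains PR 1.10, AR 1.30, VR 1.30 (subject SD
  0.05): the configured effect size whose qualitative pattern (both XR arms
  improving more than PR, indistinguishable from each other) mirrors the
  study's findings. Per-round training amplitudes follow a saturating
  exponential toward a per-arm plateau (time constant 3 rounds; plateau
  +6% PR, +18% AR/VR) with 15 mm bout noise.
- **Sway** (unreported mechanism): planar Ornstein–Uhlenbeck process
  (mean-reversion 1 s⁻¹) mixed with a deterministic 0.4 Hz circular
  oscillation; the mixing weight tunes regularity (hence ApEn) and the
  diffusion scale tunes path length. Defaults follow the printed COP table
  qualitatively: epoch durations from the printed excursion/velocity
  ratios (~21 s at baseline; 27/53/51 s post for PR/AR/VR), effective
  stochastic drive (1 − mix)·diffusion so that only the PR arm speeds up
  after training, and a lower post-training mix in the AR/VR arms so their
  sway grows more complex. The model's attainable ApEn band at m = 2,
  r = 0.2·SD is roughly 0.44–0.54, so the printed *absolute* ApEn levels
  (0.30–0.42) are not reproduced — only their ordering. This is a known
  generator limitation, not a measurement-code property.
- **Questionnaires**: latent traits are target normalized scores, mapped
  through the inverse of the 1..7 normalization before drawing items from a
  discretized truncated normal (item SD 0.9 on the 1..7 scale). Targets
  follow the printed values where available (SSQ rising after training only
  in VR; matched ITQ near 0.50; PQ 0.38 AR vs 0.67 VR; higher GEQ/UEQ in
  the XR arms). Item counts: SSQ 16 (the instrument's symptom checklist);
  ITQ 18, PQ 19, GEQ 19, UEQ 14 — administered counts are unreported, so
  these are config-driven conventions.
- **Target levels**: a bout reaches the highest target whose along-direction
  distance does not exceed the bout amplitude — the simplest deterministic
  link between amplitude and score.
- **Coordinate frame** (never fixed by the study): origin at the neutral
  seated trunk position, x toward the dominant side, y forward, meters;
  F = +y.

A single integer seed drives everything; identical configurations produce
byte-identical cohorts and byte-identical `report.json` files. For ANOVA
simulation studies (type-I error over a thousand cohorts, recovery rates
over hundreds) `simulate_metric_table()` draws the same subject-level
quantities without rendering trajectories; the trajectory path's own
measurement properties (noise-induced FRTS bias, filter behavior) are
characterized separately by the trial-level tests, so re-rendering them per
simulation replicate would add cost without information.

What the generator does *not* emulate: real marker dropout patterns,
anticipatory postural adjustments, fatigue drift across rounds, non-Gaussian
questionnaire response styles, or any force interaction with the trunk
support robot. Passing recovery tests therefore shows the pipeline measures
what the generator programs — not that the generator reproduces human data.

## Numerical choices and degenerate inputs

- FRTS ties broken by the earliest sample; empty trajectories are errors.
- Star polygons require ≥ 3 distinct non-collinear points; degenerate
  geometry is an explicit error, as are constant series passed to
  Shapiro–Wilk or groups with zero within-deviation variance in Levene's
  test (flagged, not NaN).
- Boundary tolerance for point-in-polygon classification is 1e-9 m;
  boundary counts as inside for HIAR.
- ApEn requires N > m + 1 and r > 0 (constant signals have SD 0, so the
  SD-proportional default demands an absolute r instead).
- Per-round COP epochs are simulated as contiguous 15 s recordings —
  continuous concatenation rather than per-bout epochs, one of two readings
  of the unstated epoch convention.
- 95% CI bands on per-round curves are t-based on per-round arm means.

## Problem sizes used by the test suite

The unit and property tests run the full design size where the property
depends on it (n = 21/arm for type-I error over 1000 seeded metric-level
cohorts and recovery over 200), and deliberately small cohorts (2–3
subjects/arm, shortened epochs) where the property is size-invariant
(determinism, serialization round-trips, counting invariants) — the
determinism guarantee in particular holds structurally, not statistically.
Geometry kernels are checked against a 10⁶-point Monte-Carlo area oracle, a
brute-force O(n³) hull, and a winding-number classifier; ApEn against a
naive double-loop implementation at 1e-10; the split-plot ANOVA against an
independently coded cell-mean sums-of-squares oracle at 1e-8.

## Workflow

The `analysis/` scripts run the study end to end on the synthetic cohort:
`01_simulate.R` (generate + serialize), `02_metrics.R` (metric table),
`03_stats.R` (ANOVA layer), `04_report.R` (full report with per-round
curves). `run_study()` does the same in one call; `scripts/acceptance.R`
recomputes the headline quantities from scratch for a given seed. The
package exposes functions rather than a shell CLI: the scripts and
`run_study()` are the intended entry points.

## Known limitations

- The generator's kinematic and sway magnitudes are illustrative where the
  study reports none; absolute ApEn levels are not matched (see above).
- No 3-D workspace volumes; FRTS is planar by default (the assessment is
  seated and near-horizontal), with the trajectory container carrying what
  a 3-D extension would need.
- No mixed-effects modelling or non-parametric fallbacks: the statistics
  layer reproduces the study's SPSS-style analysis plan, not a modern
  re-analysis.
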