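---
title: "Torsobarography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsobarography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its model

A subject lies supine on a capacitive pressure mat of 160 rows (cranial to
caudal) by 100 columns (subject-left to subject-right), 5.1 mm per pixel,
sampled at 10 Hz for 10 s. The dorsal imprint of the torso is a smooth
pressure field whose morphology tracks the back surface: the thoracic
kyphosis loads the upper back, the lumbar lordosis lifts the lower spine
off the mat, the paraspinal muscles leave a longitudinal intensity trough
("concave canal") over the spinous processes, the scapulae add sharp local
maxima, and the sacrum/gluteal muscles carry most of the weight caudally.
All pipeline quantities are derived from this structure; intensity is kept
in raw sensor units (prv) throughout, so every cross-subject parameter is a
ratio, a position or a slope.

One frame per measurement is analysed: the frame whose mean intensity is
the median of the per-frame means ("medial frame"), which suppresses
breathing and transient movement. For an even frame count the frame at
ascending rank ⌈n/2⌉ is taken — a deterministic convention; frames are
never averaged.

## Preprocessing

Two filtered variants are carried in parallel: the smooth image
`I = gaussian(median(frame, 15×5), 3×3, σ = 3)` for alignment, masking and
landmarks, and the lightly filtered `Is = median(frame, 5×1)` where peak
intensity and position matter (scapulae). The 15×5 median removes thin
fold artifacts of the mat; borders use edge replication (a zero border
would darken the contour the waist extraction traces; the source method
does not specify a border rule).

**Alignment.** The imprint's mirror axis is moved to the vertical image
centre by exhaustive search over integer rotations α ∈ [−15°, 15°] and
translations t ∈ [−30, 30] px of the SAD cost
ξ(α,t) = Σ |I_{α,t} − I*_α|, where I*_α is the α-rotated image mirrored
about the centre axis (column i ↦ 101 − i). An imprint whose axis sits δ
columns off centre matches its mirror at t\* = −2δ, so the applied centring
translation is t_c = round(t\*/2) = −δ. Odd t\* leaves a half-pixel
ambiguity; we round towards zero, i.e. the imprint is only moved on
evidence of a full pixel. Rotation uses bilinear interpolation about the
continuous image centre with zero fill and clipping at zero. Afterwards the
caudal-most row whose row sum exceeds tv lands on row 160, giving all
measurements a common caudal anchor.

Two consequences worth knowing:

* The *symmetry axis* is the continuous coordinate 50.5 (between the two
  central columns) — the mirror i ↦ 101 − i has its fixed axis there. All
  continuous deviations (FC5, TS1, SB2, W2, …) measure against 50.5;
  discrete left/right splits use columns ≤ 50 vs ≥ 51. With an integer
  axis of 50 every symmetric imprint would carry a spurious 0.5 px
  deviation per row.
* On an imprint with a one-sided intensity surplus (a rib hump), the SAD
  optimum trades geometric centring against intensity balance by a pixel.
  This slightly dilutes intensity-ratio parameters; it is a property of
  the published method, not of this implementation.

**Region of interest.** A torso-shaped binary template (rectangular trunk,
quarter-round shoulder caps, a concave waist inset centred near 46% of the
torso span, a slightly narrower pelvic block) is scaled by (s_j, s_i) over
0.6–1.4 and fitted by minimising the two-region absolute-deviation energy
Σ_inside |I − mean_in| + Σ_outside |I − mean_out| — a piecewise-constant
(Chan–Vese style) criterion. The search is coarse-to-fine: step 0.1, then
0.02 within ±0.08 of the coarse optimum; tests verify the optimum beats an
exhaustive coarse grid. The exact template of the source system is not
recoverable; ours is an explicit parametric stand-in. After fitting, the
mask is widened laterally by 2 px (`roi_margin_px`): its job is to exclude
arms and head, and without the guard ring the energy-minimising mask hugs
the imprint edge and would clip the very contour that the waist and
reference-position modules trace.

## Landmarks

The torso start j_ts is the first row whose ROI row sum exceeds
tv = 7000 prv (the stated maximum noise amplitude of a row sum). The mean
intensity curve z(j) averages the 31 columns centred on the axis of the
*unmasked* smooth image (the published definitions use I here and the ROI
for j_ts; we keep that asymmetry as printed). Extreme-value analysis on
z gives the thoracic maximum, lumbar minimum and sacral maximum: local
maxima of a lightly smoothed z are paired so that a genuine trough (below
both peaks, strictly between them) separates them; peak locations are then
refined on the raw curve. Ties break towards smaller j. Region boundaries
are strict crossings of z with the reference value v_z (mean of z over
[j_ts, j_lmin]): first row at/after the crossing on the far side. A curve
that merely touches v_z (e.g. constant) has no crossing and raises a
detection error rather than fabricating a boundary.

Lateral reference positions i_l and i_r are the contour points of maximum
concave curvature: the boundary of the non-zero ROI is traced per row, a
three-point second difference over a ±5-row arc (after light smoothing)
scores curvature towards the torso interior, and the apex is refined to
the most medial raw contour point near the curvature peak. A contour with
no concave excursion (rectangle) is an error.

Distances use the **inclusive pixel convention** (end − start + 1): it is
the only convention under which the published grand-mean distances equal
the differences of the corresponding landmark grand means
(130.2 − 31.7 + 1 = 99.5), and the acceptance suite pins it.

## Parameters

* **FC1–FC7** quantify the frontal curve L_fc(j): per-row minima of the
  ROI within the ±15-column central band, the minimum closest to the axis
  (ties to the smaller column), smoothed by a fifth-degree least-squares
  polynomial; a linear fit gives the generalised orientation. FC4 is
  reported as a magnitude with the signed value kept as a diagnostic (the
  printed formula lacks outer bars but is described as a deviation).
* **SC1–SC8** characterise z(j): linear regressions on the four landmark
  intervals give slopes whose angle differences arctan((m₁−m₂)/(1+m₁m₂))
  are *associated with* (not equal to) the kyphosis and lordosis angles;
  values are radians of slope space, unitless by construction. If
  1 + m₁m₂ = 0 the angle is ±π/2 by continuity, with a warning. SC6 is
  kept with its printed sign (negative when the thoracic maximum is both
  higher and cranial of the lumbar minimum). The thoracic and lumbar sums
  share the transition row j_tl, exactly as defined.
* **S, SB** (shoulders, scapulae): the shoulder regions are the left and
  right thirds of the upper third of the segment AS; each is thresholded
  at its own mean, the first supra-threshold row per column forms the
  contour, and both contours are ordered lateral→medial before regression
  so the slope coefficients are comparable between sides. Scapula centres
  are located on `Is` within the thoracic rows, excluding the central
  quarter torso width, after presegmentation at tv and a 3×3 σ = 2
  Gaussian; of the two highest maxima per side, a composite rank score
  (lateral offset + intensity, lateral wins ties) picks the centre — the
  published rule names both properties without ordering them.
* **TS1–TS5** (torso symmetry): centre-of-pressure deviation summed from
  j_ts to j_l (the printed sum leaves its start row undefined; the torso
  start is used and the signed sum is kept as a diagnostic), max ratios
  over the thoracic and thoracolumbar side segments, and the mean
  percentage difference between the mean-thresholded imprint and its
  mirror over pixels where both are positive.
* **W0–W4** (waist): per side, the outermost supra-threshold column per
  row over the lumbar span ±10 rows (threshold: mean positive intensity of
  the lateral third of that side) gives the boundary; a quartic fit is
  evaluated over the lumbar rows and its most medial excursion is the
  waist centre; a quadratic fit supplies the coefficients compared by W4.
* **P0–P4** (pelvis): slope of z over [j_l, j_smax]; adaptive mean
  segmentation of the sacral span split at the axis gives per-side upper
  and lower edges (P2) and intensity sums/means (P3, P4).

A parameter family that fails (e.g. no concave waist) is recorded as a
per-family failure with NA values; the remaining families are unaffected.

## Reliability statistics

ICC(1,1) is the one-way random-effects, single-measurement intraclass
correlation (MSB − MSW)/(MSB + (k−1)·MSW). The 95% CI is the exact
F-interval: F = MSB/MSW on (n−1, n(k−1)) degrees of freedom,
F_L = F/q_{0.975}, F_U = F·q'_{0.975} (swapped df), each transformed
through (F′−1)/(F′+k−1). Within-subject SD uses the sample (k−1) divisor;
CV is SD over the magnitude of the subject mean, in percent, with
zero-mean subjects excluded. Classification bands: ICC ≥ 0.9 excellent,
≥ 0.75 good, ≥ 0.5 moderate, else poor; CV ≤ 10 / 20 / 30%; SD ≤ 1 / 2 /
3 px (boundaries inclusive).

## The phantom: what it emulates, and what a green test establishes

The generator superposes smooth structures on a torso-shaped support:
plateau (8000 prv), thoracic bump, a lumbar depression with a slow caudal
recovery (the lordosis gap), a side-resolved sacral complex (central bump
plus broad gluteal mounds rising steeply at the gluteal crease), scapula
peaks, shoulder caps, per-side waist insets, and a carved canal following
a configurable lateral-deviation polynomial. Placement (integer rotation
and translation), additive Gaussian sensor noise and optional thin fold
lines model the measurement. The canonical row layout and intensity scale
were calibrated once to the published grand means (torso start ≈ 31,
thoracic maximum ≈ 52, lumbar minimum ≈ 90, sacral maximum ≈ 131 after
anchoring; scapula windows ≈ 1.3·10⁴ prv) and the noise σ = 150 prv to the
stated row-sum noise ceiling of 7000 prv.

Within-subject variation in `generate_study()` redraws the placement
(rotation sd 3°, translation sd 4 px, both truncated) and jitters the
amplitude knobs by ~2%, emulating repositioning between repetitions;
between-subject variation draws the anatomy knobs from population
distributions. Recordings default to 3 frames with a ±1% breathing
modulation — the protocol records 100 frames, but additional
statistically identical frames only cost runtime.

The phantom does **not** model tissue deformation, pad elasticity, knee
angle variation, clothing folds beyond thin lines, or any coupling between
anatomy knobs. A green recovery test therefore establishes that the
pipeline inverts its own generative family under the stated noise — not
that it measures human posture correctly.

Known quantitative limits, measured and frozen into the tests:

* **Anchor bias.** Under noise the caudal row-sum crossing sits 1 px
  caudal of its noise-free position and the v_z-crossing boundaries
  jitter by up to 2 px, so landmark recovery is within ±3 px (mean
  absolute error ≤ 2 px over the fuzz corpus).
* **W4.** The adaptive-threshold waist boundary tracks ln(intensity) as
  well as geometry, and the fit span [j_tl−10, j_l+10] brackets the
  thoracic flank and sacral rise; this adds a common concave component
  (~7·10⁻⁴ px/row²) to both side contours and biases the curvature ratio
  towards 1 by 15–20% at ratio 2. Tests assert monotone, near-linear
  transfer within 25%.
* **P2.** The sacral span starts at j_l, which itself shifts when one
  side's sacral complex is moved; the edge sum recovers 2k within
  [2k−2, 2k+1].
* **Interpolation.** Bilinear derotation at |α| ≥ 9° alone produces
  TS5 ≈ 0.7% and FC5 ≈ 1.5 px on an exactly symmetric imprint; the
  symmetry-identity suite therefore runs at the repositioning range
  (|α| ≤ 6°).

## Numerical choices

* Exhaustive integer grids for alignment (the admissible set is 31 × 61;
  the published description says "iteratively", but enumeration is exact
  and cheap, and the tests define the optimiser *as* enumeration so any
  future speed-up must match it).
* Ties: medial frame (lower rank), extrema (smaller j), canal minima
  (smaller i), t\*/2 rounding (towards zero).
* Polynomial fits use QR (`lm` on raw powers); the test oracles solve
  centred normal equations.
* Degenerate inputs raise typed errors (`input error`, `format error`,
  `detection error`, `fit error`, `alignment error`) rather than
  returning silently plausible values; the CLI maps them to exit codes.

## Configuration

`torso_config()` exposes: `tv` (7000 prv; also the bottom-anchor
threshold), `delta_iz` (30 px central band), `alpha_range`/`t_range`
(15°/30 px), `scale_lo`/`scale_hi`/`scale_step` (0.6/1.4/0.02),
`roi_margin_px` (2 px guard ring), `curvature_window` (5 rows), and the
mat geometry (`n_rows`, `n_cols`, `pixel_mm`, `sample_rate_hz`). The tv
default is tied to the vendor's raw intensity scale; phantom units were
calibrated to the same scale so the default applies to both.
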