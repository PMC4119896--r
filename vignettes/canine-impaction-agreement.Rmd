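---
title: "Methods: scoring impacted canines in 3D and 2D and measuring their agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring impacted canines in 3D and 2D and measuring their agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canimpact)
```

## The measurement problem

An impacted maxillary canine can be characterised on a CBCT volume by two
landmarks — the cusp tip and the root apex — placed in a patient-level
anatomical frame. The KPG index condenses that 3D position into a severity
total by scoring each landmark's displacement on each anatomical axis from 0
to 5 and summing the six subscores. The older panoramic measures condense
the same anatomy after projection onto a 2D film: a vertical distance
(Stewart), a mesiodistal sector (Ericson–Kurol), and an inclination angle
(α). This package implements both layers plus the agreement statistics that
connect them, and a synthetic cohort generator so every stage is testable
without images.

## The 3D scoring model

**Coordinate convention.** Right-handed, millimetres; x mesiodistal with the
dental midline at `midsagittal_x` and mesial displacement increasing x on
the right-normalised side; y vertical, increasing apically, with the
occlusal plane's reference points defining y-distance; z anteroposterior.
Left-sided canines are mirrored about the midsagittal plane before scoring,
so the two sides are scored identically (a property the test suite checks by
mirroring random cases).

**Displacements.** The anatomy frame carries explicit ideal landmarks for
both the cusp tip and the root apex (`ideal_cusp`, `ideal_apex`). For each
landmark the three displacement magnitudes are measured relative to its own
ideal reference: the mesiodistal offset |x − x_ref|; the change in
perpendicular distance from the occlusal plane; and the change in
perpendicular distance from the occlusal reference arch in the axial (x, z)
view, with the arch represented as a piecewise-linear curve through ≥ 4
ordered control points. Because the ideal cusp lies on the occlusal plane
and on the arch, its displacements reduce to plain distances from plane and
arch; referencing the apex to its own ideal point (rather than to the
occlusal plane, from which a healthy apex sits ~25 mm away) is what makes an
ideally positioned canine score 0 on all six axes. Anchoring the x-origin in
an explicit landmark, instead of inferring an "ideal position" from the
arch, keeps scoring deterministic.

**Zone boundaries.** The original index defines its 0–5 zones graphically
against adjacent anatomy and publishes no millimetre values, so boundaries
here are configuration with shipped defaults: 2, 4, 6, 8, 10 mm on x and z
(roughly quarter-of-a-tooth-width steps around typical incisor and canine
widths) and 3, 6, 9, 12, 15 mm on y (vertical displacements run larger).
They are calibration surrogates, not a claim about the original instrument;
any strictly increasing 5-vector per axis and landmark is accepted. A
displacement exactly on a boundary takes the *lower* subscore — a
deterministic tie-break chosen so that boundary values behave like zone
upper edges.

**Category bands.** Original: 0–9 easy, 10–14 moderate, 15–19 difficult,
20–30 extremely difficult. Modified: easy shrinks to 0–6, moderate widens to
7–14. Dichotomous: ≤ 14 easy-moderate, ≥ 15 difficult–very difficult. The
bands partition 0–30 with no gaps or overlaps under every scheme (tested
exhaustively over all 31 totals).

## The 2D measures

Stewart's distance is the perpendicular distance from the cusp tip to the
*infinite* line through the molar and incisor occlusal reference points; the
infinite line is used because nothing in the measure's definition restricts
the foot of the perpendicular to the segment, and a cusp can project beyond
the molar. Classification is `shorter` below 14 mm and `longer` at 14 mm or
more — the tie goes to `longer` because the rule is stated as "14 mm or
more".

The Ericson–Kurol sector counts, mesially, the four boundaries (lateral
incisor distal surface, lateral incisor midline, lateral incisor mesial
surface, central incisor midline) at or below the cusp tip's x position.
Only the dichotomy at the lateral incisor midline carries prognostic weight
(sectors 1–2 easy, 3–5 difficult), but the full five-sector scheme is
exposed with configurable boundaries since it is the standard instrument. A
cusp exactly on the lateral midline is *not* distal to it, so the tie
resolves to the mesial, difficult side.

The α-angle is folded to [0, 90°]: an inclination has no sign, so the angle
is invariant to reversing either the canine axis or the midline direction
(both symmetries are property-tested, as is invariance of both planar
measures under random rigid transforms). Crescini's traction rule is applied
as weeks = α/5 with zero intercept; with no stated intercept the value is
documented as an estimate of *additional* traction time rather than an
absolute duration.

## Agreement and accuracy statistics

Cohen's kappa uses the standard marginal-product chance correction; the
degenerate case of two identical constant rating vectors returns 1 (perfect
agreement) rather than 0/0. Reliability kappas are computed on the
dichotomised category labels per index, not on raw scores, because
categories are what the indexes report clinically; Kendall's W instead uses
the raw numeric scores (KPG total, Stewart mm, sector number) ranked within
rater, with the standard tie correction `W = 12S / (m²(n³−n) − mΣT_j)` — the
implementation is cross-checked in the tests against the tie-corrected
Friedman statistic (χ²_F = m(n−1)W).

On 2×2 tables, φ = (ad − bc)/√(r₁r₂c₁c₂), and the uncorrected χ² satisfies
χ² = Nφ² identically (asserted to 1e−12 in the tests, alongside the
equivalence of φ with the Pearson correlation of the expanded 0/1
indicators). The Yates statistic shrinks |ad − bc| by N/2 before squaring,
floored at zero. Zero-margin tables make φ and χ² undefined: those are
signalled as errors (or as `NA` plus a `defined` flag inside pipeline
reports), never silently returned as numbers. Diagnostic accuracy follows
the standard confusion-matrix definitions with an explicit `positive_label`
and an explicit choice of which side is the reference standard; the shipped
fixtures designate the first category (shorter / easy) as positive and the
column index as reference, the only orientation consistent with the
published accuracy values they encode. When the two dichotomies carry
different wordings (shorter/longer vs easy/difficult) categories are aligned
by position.

The kappa sample-size uses the Bloch–Kraemer large-sample variance of the
binary intraclass kappa, Q(κ) = (1−κ)[(1−κ)(1−2κ) + κ(2−κ)/(2p(1−p))], in
n = ⌈((z_α√Q₀ + z_β√Q₁)/(κ₁−κ₀))²⌉. For the design values used throughout
(κ₀ = 0.40, κ₁ = 0.70, prevalence 0.70, two-sided α = 0.05, power 0.80) this
gives n = 76 subjects. Published sample sizes for this design vary with the
variance approximation chosen, which is why the formula is isolated behind
one function; differences below `min_difference = 1e-3` in |κ₁−κ₀| raise an
error rather than returning an astronomically large n.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions: 105 impacted canines,
patients bilateral with probability 15/90 (bilateral canines share a patient
id), three raters, two timepoints. Displacement magnitudes are truncated
normals (nonnegative mm) applied mesially, apically and palatally: x
location 8, scale 5; y location 8, scale 4; z location 3, scale 2.5. These
were chosen once so that the simulated cohort spans all five sectors and
produces a realistic minority (~20–25%) of `longer`/difficult cases; other
families (half-normal, uniform, exponential) are pluggable. The root apex
inherits a uniform 0.1–0.5 fraction of the cusp displacement and is then
placed at a uniform 22–28 mm axis length from the cusp, keeping the tooth
anatomically coherent (roots displace less than crowns).

The panoramic projection is `x' = m(x + c·x·|z|)`, `y' = m·y` with
magnification m = 1.25, horizontal nonlinearity c = 0.003 per mm, a +5°
opening of the projected inclination, and 0.5 mm Gaussian image-formation
noise on the canine landmarks — parametric stand-ins for the documented
panoramic distortions of the anterior maxilla (overestimated angles and
distances, nonlinear horizontal stretch). It is a test harness, not a
focal-trough model: it does not emulate ghost images, out-of-focus blur of
proclined incisors, or patient positioning error. Rater noise is Gaussian on
the landmarks each rater re-measures (0.75 mm, 3D for the KPG layer and 2D
for the panoramic layer), independent per rater × timepoint. Consequently,
passing tests show that the statistics respond correctly to landmark-level
measurement noise under this projection model; they cannot show how the
indexes behave under real-image artefacts or systematic inter-centre
differences.

Randomness follows a named-substream discipline: case generation, the
projection, and each rater × timepoint draw from sub-seeds derived from the
master seed and a label path, so adding raters or timepoints never perturbs
the generated anatomy (tested by comparing 2- and 3-rater panels).

## Numerical choices and degenerate inputs

Point-to-plane and point-to-line distances use exact closed forms with a
1e−9 collinearity guard; the axial arch distance is the minimum over the
polyline's segments. Boundary ties are resolved as described above
(subscore: lower; 14 mm: longer; lateral midline: mesial). Metric
comparisons against 3-decimal published values use round-half-away-from-zero
to match the usual reporting convention (base R rounds half to even).
Out-of-range inputs (negative displacements, totals outside 0–30, α outside
[0, 180)) raise errors rather than clamping.

## Problem sizes used by the test suite

Property tests run on seeded batches sized for tightness of the property,
not for realism: 1,000 random tables for the φ/indicator-correlation
identity, 200 displacement/threshold draws for subscore monotonicity, 50
random rigid transforms, and Monte-Carlo agreement runs of 200 cases × 3
raters × 2 timepoints across five rater-noise levels (0, 0.5, 1, 2, 4 mm),
over which the median intrarater kappa is checked to be non-increasing. The
zero-noise runs are exact, not statistical: kappa and W equal 1 identically.

## Known limitations

* The millimetre zone boundaries of the KPG subscores are surrogates; any
  quantitative claim about the original instrument's zones is out of scope.
* The published Yates χ² statistics and correlation p-values attached to the
  packaged contingency tables cannot be derived from the packaged counts
  themselves (the counts imply substantially larger χ² values);
  `reproduce_tables()` therefore asserts only the derived accuracy metrics
  and surfaces the χ²/p discrepancy as a warning.
* The α-angle layer is computed and summarised but never dichotomised or
  cross-tabulated, as it has no accepted cut-off.
* Reliability ranges observed on real raters cannot be reproduced from
  synthetic noise parameters; the synthetic panels support property checks
  (perfect agreement at zero noise, monotone degradation), not quantitative
  reliability claims.
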