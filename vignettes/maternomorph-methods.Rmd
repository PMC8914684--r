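---
title: "Modelling maternal body shape: statistics, morph space and measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling maternal body shape: statistics, morph space and measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maternomorph)
```

maternomorph predicts the body measurements of pregnant and postpartum
women from a handful of covariates and turns those predictions into a 3D
body mesh. This vignette is the package's own account of the models it
implements, the parameters that matter, and the design decisions taken
where the method left room.

## The statistical layer

### Circumference regressions

Five circumferences (chest, waist, hip, upper arm, thigh; cm) are linear
in the covariates, with fixed published coefficients:

* pregnant: `value = A*age + B*pre_weight + C*height + D*gravida +
  E*gestational_week + F*weight_gain + G`
* postpartum: `value = A*age + B*pre_weight + C*height + D*gravida +
  E*baby_weight + F*postpartum_week + G*postpartum_weight + H`

The coefficient tables ship as built-in constants
(`regression_coefficients()`); alternative tables load from CSV in the
same fixed covariate order. Defaults (age 30, gravida 1, baby weight
3 kg) apply only when a field is absent. The fitted cohorts had gravida
1–2; larger values are accepted as extrapolation. Gestational weeks are
accepted on [0, 42] and postpartum weeks clamped to [0, 24] with a
warning, matching the ranges the models were used on. A profile driven
far outside the plausible covariate range can push a predicted girth
negative; that raises an error rather than clamping, since it signals
misuse, not a measurable body.

Leg length (inseam) is not regressed on week: it was measured once per
subject and treated as static, so the package always computes it from the
non-pregnant baseline equations — four linear forms in (weight, height) —
evaluated at *pre-pregnancy* weight.

### Weight dynamics

When gestational weight gain is unknown it is predicted from the
pre-pregnancy BMI category (WHO cut points, half-open intervals
`[0,18.5) [18.5,25) [25,30) [30,Inf)` — the half-open convention closes
the printed-table gaps at 24.9→25.0 and 29.9→30.0). The IOM guidance
fixes two anchors per category: the average total gain at term (midpoint
of the recommended range, e.g. 15.455 kg for underweight) and a central
weekly rate for trimesters 2–3. The guidance does not say how gain
accrues before week 12, so the package adopts the simplest continuous
scheme consistent with both anchors: the first-trimester remainder
(`avg_total − 28*weekly_rate`) accrues linearly over weeks 0–12, then
the weekly rate applies. The curve is continuous, zero at conception,
non-decreasing, and exactly the IOM average at week 40.

Postpartum weight, when unknown, is pre-pregnancy weight plus a
per-category retention curve: quadratics in postpartum week, anchored at
week 0 to half the IOM average gain and fitted over 0–24 weeks (weeks
beyond 24 are clamped — the curves were never fit there). The six-month
anchors were derived by a rule-of-three transfer of a Taiwanese cohort's
retention onto IOM gain levels; `retention_sources()` ships the source
constants. One published inconsistency is preserved deliberately: the
normal-weight transfer computes to 2.439 kg but was published as
2.430 kg, and the published retention quadratics are what the package
evaluates. We ship the constants as printed and document the 0.009 kg
discrepancy rather than "fixing" either number.

## The morph space

A body mesh is a per-vertex affine combination of seven
topology-identical avatars: thin (base), big-breast, big-waist, big-hip,
tall, long-legs, and pregnant-thin. Output vertices are

`P = (1 − ΣK)·thin + K0·pregnant_thin + K1·big_breast + K2·big_waist +
K3·big_hip + K4·tall + K5·long_legs`

with the sum over the applicable weights (postpartum mode has no belly
term, K0 ≡ 0). Each weight is a base value plus a correction:

* base weights are fixed affine rescalings of the *non-pregnant baseline*
  measurements between the thin avatar's dimension and the morph
  target's maximum: chest 57→200, waist 40→160, hip 68→180, height
  165→199 with an extra 1.36 gain, and inseam anchored at 78 over the
  48–120 range. The inseam anchor (78) is not the thin avatar's actual
  leg length (≈73); the printed constants are shipped as they are, and
  the calibration stage absorbs the offset. The belly base weight K00 is
  identically zero: all pregnancy change is carried by the corrections.
* corrections `AlpX` are quadratics in pre-pregnancy BMI whose three
  coefficients are themselves quadratics in the week — a 15-row
  (postpartum) or 18-row (pregnant) tensor of constants. Weeks are
  clamped to the tensor's fitting domain (gestational 12–40, postpartum
  0–24) before polynomial evaluation; below 12 gestational weeks the
  assembled belly correction is then scaled by `week/12` (raw week), so
  the belly grows in smoothly from zero. We apply that scaling last, to
  the assembled correction — the literal reading of the published rule.

Two points were genuinely open and are package decisions: the BMI
entering the correction polynomials is the *pre-pregnancy* BMI in both
modes (the published figures index body types by pre-pregnancy BMI
category, and the weight-gain machinery is driven by it), and the blend
summation index runs over the six (five postpartum) morph weights.
Weights outside a sanity band (each K in [−0.5, 1.5], thin coefficient
≥ −0.5) produce warnings, never clamping — the published model shows no
clamping either.

## The avatar set

The original avatars were commercial assets and cannot be
redistributed, so the package generates a synthetic stand-in: seven
procedural humanoids lofted from horizontal elliptical cross-sections
(torso+head column, two legs, two slightly abducted arms), sharing one
topology. Each ring's polygon is scaled so its perimeter equals a target
girth profile exactly, which pins the documented anchors by
construction: thin ≈ 57/40/68 chest/waist/hip, inseam 73, height 165;
big-breast chest ≈ 200; big-waist waist ≈ 160; big-hip hip ≈ 180; tall
height ≈ 200 (a uniform scaling of thin); long-legs inseam ≈ 120.
Generation verifies every anchor against the measurement module to
within 2% and fails loudly otherwise.

Two generator details matter downstream. Landmarks that are band
*maxima* (chest, hip) can be hit with a local enlargement, but the waist
landmark is a band *minimum*: raising the measured waist of the
big-waist avatar requires lifting the entire waist band, so that avatar
carries a flat 160 cm plateau across the band, decaying in the gaps
between measurement bands. Residual cross-talk (the plateau tails raise
a blend's measured chest and hip somewhat) is deliberate and is exactly
what the calibration stage compensates. Second, the arms are generated
slightly abducted and anchored relative to the crotch so chest-level
cross-sections separate the torso loop from the arm loops in every
blend.

The avatars are schematic: no hands, feet, facial features, or surface
detail, and the big-breast enlargement is a smooth anterior-shifted
ellipse rather than sculpted anatomy. They are dimensionally faithful
morph targets, not portraits; tests passing on them show the pipeline's
numerics, not realism of any individual mesh.

## Mesh measurement

Girths are read as a tape measure reads them: the convex-hull perimeter
of a horizontal cross-section loop (a tape bridges concavities such as
the inter-breast notch); the raw polygon perimeter is available via
`measure_config(method = "polygon")`. Cross-sections are assembled from
triangle–plane segments connected by shared mesh edges — exact
connectivity, no coordinate snapping.

The measurement heights are a package convention (the published method
never defines them): height is the maximal y; inseam is the crotch
height found by bisecting for the level where the single torso loop
splits into two leg loops; chest is the maximal torso girth in the band
0.67–0.78 of height, waist the minimal in 0.565–0.635, hip the maximal
in 0.45–0.535 (intersected with the supra-crotch region); upper arm is
the arm-loop girth at 0.75 of height and thigh the leg-loop girth 5 cm
below the crotch. The bands were chosen to bracket the anatomical levels
of the bundled avatars while leaving decay gaps between neighbouring
bands — with contiguous bands, a band-wide feature of one landmark
(the big-waist plateau) would leak into the neighbouring landmark's
extremum and couple the morph axes unnecessarily. All bands are exposed
in `measure_config()`. Within a band the extremum is found by a coarse
scan followed by local refinement of *every* scanned local extremum;
refining only the global scan winner would make the measured value jump
discontinuously when two competing local maxima trade places, which the
calibration optimizer cannot tolerate.

## Calibration

`calibrate_alp()` re-derives the correction tensor for any avatar set:
per (BMI, week) grid cell it solves a bounded nonlinear least-squares
problem for the corrections that make the blended mesh's measured chest,
waist, hip, inseam and height match the statistical targets, then
condenses the per-cell corrections into the tensor by quadratic fits
(in BMI per week, then in week per tensor row). Upper arm and thigh are
excluded from the objective: no morph target drives them, and they were
the published model's weakest dimensions too.

The default inner solver is a damped Gauss–Newton iteration with box
projection onto [−1, 1], a deterministic start at zero, forward
differences taken with a step large enough (0.02) to stay above the
girth-search discretization, and damping-reset restarts; a bounded
cyclic coordinate-descent solver (`method = "coordinate"`) is available
as a simpler alternative. Gauss–Newton was adopted as the default
because it reaches per-cell residuals below 0.01 cm in a few dozen
objective evaluations where coordinate descent needs hundreds, and cell
residual accuracy is what bounds tensor-recovery accuracy.

Identifiability differs between modes. Postpartum calibration solves
five corrections against five measurements — a well-posed square system,
and a known tensor pushed through the forward model is recovered to
better than 1e−3 per correction. Pregnant calibration has six
corrections but still five measurements: the belly weight's measurable
effect lies in the span of the waist/chest/hip weights, so a
one-dimensional null space exists and individual corrections are not
identifiable — only their measurable effect is. The package therefore
validates pregnant calibration in measurement space (blended meshes
reproduce the statistical targets), not in parameter space.

The default grid is 4 BMI values spanning the four categories (17, 22,
27.5, 32) by 4 weeks (gestational 12–36, postpartum 0–24), for a
reference subject of height 158 cm — a deliberate desk-scale design:
both stages fit quadratics, for which 4 support points per axis suffice,
and the statistical targets are nearly linear in both BMI and week over
these ranges, so the quadratic condensation loses little. After
calibration against the bundled avatars, mesh-measured chest, waist,
hip and inseam track the statistical predictions with a mean absolute
relative error well under 3% across the grid — the fidelity bar the
original validation reported for pregnancy.

### Agreement statistics

`agreement_stats()` implements the comparison summary used to validate
measurement routes: per-series mean and SD (n−1), 95% confidence
intervals with the normal 1.96 multiplier (verified to reproduce the
published bounds, e.g. 90.76 from mean 94.51, SD 10.49, n = 30 — a
Student-t multiplier would not), the relative error of the means, and
the Pearson correlation. The published tables normalise the relative
error inconsistently (by the model series in one comparison, by the
manual series in another), so the denominator is an explicit
`reference` argument, defaulting to the first series.

## The synthetic cohort

`generate_cohort()` produces longitudinal records with the published
cohort structure: subject covariates drawn once from truncated normals
(printed range, mean and SD; the location parameter is solved so the
*truncated* mean matches the printed mean, which matters for the
asymmetric weight range), gravida 1 or 2, visits every 4 weeks, the
time-varying weight covariate from the weight-dynamics curves plus a
subject-level jitter, and responses from the regression tables plus
i.i.d. Gaussian noise. The protocol's reported ±2 cm interrater spread
is modelled as noise with SD 1 cm (≈95% of repeats within ±2 cm).
Dropout is independent per-visit Bernoulli; `visit_retention = "paper"`
uses probabilities matching the published per-visit counts (587 of 686
possible pregnant records). Covariates are drawn independently — the
source reports no correlation structure — and an optional correlation
would be the first thing to add for more realistic designs.

What the generator does *not* emulate: left/right limb asymmetry, twin
pregnancies, informative dropout, exercise effects, and any
covariate-dependent retention beyond the BMI category. Tests that pass
on these cohorts certify the estimation machinery (OLS recovery,
agreement statistics), not the epidemiology of any real population.

## Numerical choices and limitations

* Girth targets are met exactly at profile knots because rings are
  scaled to the *polygon* perimeter; measured girths therefore do not
  depend on ring vertex count, only band-scan resolution does.
* Crotch bisection tolerance is 0.02 cm; band refinement tolerance
  0.1 cm (0.15 during calibration, where speed matters and residuals are
  driven well below either figure).
* Problem sizes in the routine test suite: default avatar resolution
  (32 ring vertices, ≈2.8 cm ring spacing, ≈3000 vertices per mesh),
  4×4 calibration grids, 3×3 recovery grids, 60-replicate Monte-Carlo
  for the noisy OLS check at the published 587-record scale. These are
  the package's default working sizes; all are parameters.
* The regressions are linear and fitted on gravida 1–2, gestational
  weeks 12–36 and postpartum weeks 0–24; outside those ranges the
  package extrapolates (with warnings where the design said to clamp).
* The bundled avatars are synthetic; the shipped published tensors are
  kept as formula-fidelity constants, and faithful mesh output against
  the bundled avatars requires the included re-calibration.
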