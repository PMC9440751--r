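---
title: "Quantifying climbing flapping flight from stereo video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying climbing flapping flight from stereo video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climbflight)
```

## What the package computes

`climbflight` implements a complete analysis chain for upward escape flight
of butterflies (and comparable flapping flyers) filmed with a calibrated
multi-camera rig:

1. **Stereo geometry** — 11-parameter direct linear transformation (DLT)
   camera calibration from 3D–2D correspondences, linear least-squares
   triangulation of digitized pixel tracks, and wand-length diagnostics.
2. **Trajectory** — Kalman smoothing of the 3D body-centroid track,
   wingbeat segmentation from digitized stroke reversals, the eight
   per-wingbeat climb metrics, and wingbeat-normalized ensemble dynamics.
3. **Wing kinematics** — body Euler angles, stroke-plane wing Euler angles
   (stroke Φ, deviation θ, rotation H), and a 10-element blade-element
   estimate of wing speed and angle of attack α.
4. **Aerodynamics** — the weight-normalized quasi-steady thrust model
   T/mg = ½ ρ U²`_wing_` (S/mg) C~Tα~ α, morphology conversions
   (wing loading and its reciprocal S/mg), steady-climb force balance, and
   the "helicopter model" regression of climb angle on body pitch.
5. **Statistics** — sequential (Type-I) ANOVA with nested factors, MANOVA
   via Wilks' λ, phylogenetic ANOVA with a Brownian-motion simulation null,
   linear regressions, Pearson correlations, Wilcoxon rank-sum tests, and
   percent group contrasts.
6. **Synthetic data** — a ground-truthed generator of climbing flapping
   flights, camera projections and hierarchical cohorts, so that every stage
   above is testable end to end without any video data.

## Coordinate conventions

The world frame is right handed with z up; gravity acts along −z. Body
orientation uses the intrinsic Z(yaw)–Y(pitch)–X(roll) sequence with the
body x-axis along the long axis toward the head; positive pitch β raises the
head, so β = 90° points the body straight up.

The stroke plane of each wing is the plane normal to the body long axis
through that wing's hinge; hinges are fixed in the body frame. Within the
stroke plane the stroke angle Φ is measured from the lateral (transverse,
body-y) axis, positive dorsal. This lateral zero was chosen over a ventral
reference because it makes bilateral symmetry exact: a symmetric stroke uses
identical (Φ, θ, H) on both sides, with the geometry mirrored across the
body x–z plane. The deviation angle θ is the elevation of the span axis out
of the stroke plane, positive toward the head. The rotation angle H pitches
the chord about the span axis; at H = 0 the chord lies along the body long
axis (wing surface perpendicular to the stroke plane), so a wing swept
through the stroke plane at H = 0 meets the air at α = 90°, and the
geometric pitch of a sweeping wing is 90° − H. All angles are degrees at
the interfaces and radians internally.

The angle of attack is defined between the wing *plane* and the velocity
vector of the blade element, α = asin(|v·n̂|/|v|) ∈ [0°, 90°]; it is
invariant to rescaling of the velocity and undefined (flagged `NA`) when an
element is momentarily at rest.

## Per-wingbeat climb metrics

A wingbeat runs from one top stroke reversal to the next (downstroke first),
mirroring how reversals are digitized from video. For each wingbeat the
package reports: frequency f = 1/Δt; the horizontal distance ΔX~hor~ (norm
of the net horizontal displacement), the signed net vertical displacement
ΔX~ver~, and the 3D path length ΔX~total~; the corresponding wingbeat-mean
speeds U = ΔX/Δt; and the climb angle γ~climb~ = atan(U~ver~/U~hor~).
γ~climb~ is computed from the wingbeat-mean velocity components, not as a
mean of per-frame angles, and U~hor~ is a magnitude, so γ~climb~ ∈
[−90°, 90°]. Path length ≥ chord implies
ΔX~total~ ≥ √(ΔX~hor~² + ΔX~ver~²), with equality for straight segments.

Ensemble dynamics (mean traces over wingbeats) normalize time separately
within the downstroke and upstroke by linear resampling, then use a
pointwise Student-t 95% confidence interval across wingbeats. The CI is
taken across *wingbeats* (not flights or individuals); with a single
wingbeat the CI is flagged undefined rather than fabricated.

## Kalman smoother

The smoother is a per-axis constant-acceleration Kalman filter (state:
position, velocity, acceleration; white jerk process noise) followed by a
Rauch–Tung–Striebel fixed-interval pass — the appropriate choice for
offline, fixed-length recordings. Defaults: process noise 100 m s⁻³
(keeps within-wingbeat speed oscillations — accelerations of order
5–10 m s⁻² reversing every half stroke at ~4 Hz — essentially unsmoothed),
observation noise 2 mm (the triangulation residual scale of a
three-camera, ~1.5 m, ~800 px-focal rig at half-pixel digitizing noise).
Missing frames receive prediction-only updates, so short gaps are bridged by
the dynamics. On noiseless constant-acceleration tracks the smoother is
exact to numerical precision after a short burn-in (≈30 frames at 240 fps)
while the initial diffuse prior washes out; the tests therefore assert
exactness after burn-in. The smoother is verified against an independent
oracle: the batch MAP solution of the joint linear-Gaussian system on a
small instance.

## Blade-element analysis

Each wing is a rigid flat plate described by a 41-point planar outline with
the hinge at the local origin; it is divided into 10 equal spanwise strips,
and each strip's area centroid (spanwise and chordwise) is found by
integrating the outline chord profile. Element velocities are obtained by
central differences of the element world positions at the frame rate
(one-sided at segment ends), which combines body translation with body and
wing rotation without requiring an explicit angular-velocity estimate.

The wingbeat-level summaries are: α~wingbeat~ — the blade-element mean α
evaluated at the temporal midpoints of the downstroke *and* upstroke,
averaged, then averaged within a wing pair (mid-stroke is where force
production peaks; using both half-strokes avoids privileging one);
U~wingbeat~ — the mean element speed over all elements, wings and frames of
the wingbeat; β~wingbeat~ — the mean body pitch; and the stroke amplitude
A~Φ~ = max Φ − min Φ. If α is undefined exactly at a mid-stroke frame the
nearest defined frame is used and recorded.

## Thrust model and morphology

The quasi-steady thrust model is implemented as
T/mg = ½ ρ U²~wing~ (S/mg) C~Tα~ α, with the conventional ½
dynamic-pressure factor and a small-angle linear thrust coefficient
C~T~ = C~Tα~·α (α in radians). C~Tα~ defaults to 1 rad⁻¹ and is
configurable, since its value is wing-geometry specific; ρ defaults to
1.17 kg m⁻³ (warm air at ~450 m elevation) and g to 9.81 m s⁻². Morphology
enters through the weight-normalized wing area S/mg (m² N⁻¹), computed from
field units (wing area in cm², mass in g) with exact SI conversion; wing
loading is its exact reciprocal.

## Statistics

* **Sequential ANOVA.** The microhabitat effect is tested with Type-I
  (sequential) sums of squares, microhabitat entered first, then species,
  individual, flight and wingbeat index, each F tested against the residual
  mean square. All factors are fixed; a mixed model is deliberately out of
  scope. The test is exactly calibrated under the iid Gaussian null (the
  acceptance checks verify a 5% type-I error); note that when true random
  species effects are present, testing microhabitat against the residual is
  anticonservative — a known property of fixed-effect nesting, inherited by
  design.
* **MANOVA.** Wilks' λ = det(W)/det(W+B) with Rao's F approximation,
  computed directly from the cross-product matrices so the single-response
  case reduces exactly to one-way ANOVA (λ = 1/(1 + F·df₁/df₂)).
* **Phylogenetic ANOVA.** The observed one-way F on species means is
  compared with F values from traits simulated under Brownian motion on the
  supplied tree (default 10,000 simulations), with the +1 finite-sample
  correction; the BM rate is estimated from the tips by GLS, though F is
  scale-free so the p-value does not depend on it. On a star tree this
  reproduces ordinary ANOVA; on trees whose clades align with the groups it
  correctly absorbs clade-level drift. Branch lengths must be supplied by
  the user; the bundled seven-species default uses plausible relative
  depths and unit-order branch lengths as a documented fallback.
* **Wilcoxon rank-sum.** Exact two-sided p for combined n ≤ 25 without
  ties, normal approximation with tie correction otherwise.
* Percent group contrasts are reported as 100·(a − b)/b with rounding
  matched to the reporting precision requested by the caller.

## The synthetic-data generator

`simulate_flight()` produces an articulated body with four rigid flat-plate
wings. The body follows a configured climb-angle/speed profile whose
position, velocity and acceleration are analytic and mutually consistent
(no finite differencing in the ground truth), including an optional
within-wingbeat sinusoidal speed modulation. Wing angles follow minimal
periodic profiles consistent with observed butterfly strokes: a sinusoidal
stroke (peak-to-peak amplitude A~Φ~, default 114°), a double-frequency
smooth deviation (figure-of-eight), and a sinusoidal rotation whose sign
flips between half-strokes. Defaults emulate the study conditions: 240
frames s⁻¹ recording, ~3.85 Hz wingbeats (0.26 s), body pitch 67°, speed
1.56 m s⁻¹, climb angle 46.7°, filmed by three ~orthogonal 848×480 px
cameras at ~1.5 m. Still air is assumed (no wind was reported for the
insectary setting emulated).

`generate_cohort()` draws hierarchical per-wingbeat records:
group mean + species deviation (Brownian motion on the tree, scaled to its
configured variance fraction) + individual + flight + wingbeat Gaussian
deviations, with the variance partition (species 0.15, individual 0.25,
flight 0.20, wingbeat 0.40 by default) chosen to reflect the strong
inter-individual and inter-wingbeat variability reported for real climbing
flights. Group means and SDs default to the published values (γ~climb~
46.7±17 vs 36.5±16°, U~total~ 1.56±0.56 vs 1.32±0.49 m s⁻¹, β 67±9 vs
44±10°, wing area 100.42±19.27 vs 79.28±21.15 cm², A~Φ~ 114±19 vs 128±26°,
…). Counts default to 2 canopy species × 5 individuals × 4 flights × 3
wingbeats and 5 understory species × 3 × 2 × 3 (120 + 90 wingbeats),
rounding the real sampling depth (106 + 77 wingbeats over 26 individuals)
to a balanced integer design. Mass is not printed in the source tables; the
default mass means (0.457 / 0.465 g) are obtained by inverting the printed
wing areas and weight-normalized wing areas, and S/mg is always *computed*
from the drawn mass and area so morphology is internally consistent.

What the generator does **not** emulate: wing deformation (real wings
deform substantially; the flat-plate model is a deliberate simplification),
lens distortion (pixels are assumed pre-undistorted, keeping the DLT
linear), camera desynchronization, digitizing outliers (noise is Gaussian),
wind, and any within-flight correlation structure beyond the flight-level
random effect. Passing tests on synthetic data therefore validate the
geometry, estimators and statistics — not the biological realism of any
particular wing-kinematics profile.

## Numerical choices

* DLT estimation fixes the 12th (constant) coefficient to 1, solves the
  homogeneous system by SVD after similarity pre-normalization of points
  and pixels, and refuses < 6 or coplanar control points. Because the L12=1
  scaling leaves the sign of the projection denominator arbitrary, each
  camera stores the denominator sign of in-front points explicitly.
* Triangulation is the linear (algebraic) least-squares solution; frames
  seen by fewer than two cameras are reported missing, never interpolated.
* Landmarks behind a camera are flagged invisible, not projected; points on
  a camera's principal plane (zero denominator) are flagged invalid.
* Euler decompositions clamp arguments of asin to [−1, 1]; the stroke angle
  is flagged undefined when the span axis is parallel to the body axis, and
  the body decomposition flags (but still returns) near-gimbal pitch.
* Degenerate statistics inputs error loudly (constant regressors, zero
  residual df, empty groups, mismatched tree tips) rather than returning
  NaN; a constant ANOVA response reports zero SS with F = 0, p = 1.

## Problem sizes used by the tests and acceptance script

The validation suite simulates three-wingbeat flights (~190 frames at
240 fps), uses 50-seed Monte-Carlo ensembles for smoother gains, 100-seed
ensembles for calibration RMSE, 1,000 replicates for the ANOVA and
phylogenetic-ANOVA type-I calibrations (199 BM simulations per replicate,
which makes the attainable p-values a uniform grid so the 5% level is
exact), and n = 120 datasets for the regression-strength recoveries; these
sizes give Monte-Carlo standard errors comfortably inside the asserted
bands while keeping a full run to a few minutes on one core.

## Known limitations

* The sequential fixed-effects ANOVA is anticonservative for the top-level
  factor when species-level random variation exists (see above); the
  phylogenetic ANOVA is the principled alternative at the species level.
* A~Φ~ from `max(Φ) − min(Φ)` is slightly biased low when stroke reversals
  fall between video frames (≤ 0.2° at the default discretization).
* The blade-element velocities use frame-rate finite differences; at 240 fps
  and ~4 Hz wingbeats the induced bias is ≪ 1% of element speed, but very
  low frame rates would need analytic angular velocities.
* `wilcox.test`'s normal approximation is used whenever ties are present,
  including tiny samples, matching common practice for continuous metrics
  where ties are measure-zero.
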