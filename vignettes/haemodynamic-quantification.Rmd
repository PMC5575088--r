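---
title: "Quantifying aortic haemodynamics and validating predicted outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aortic haemodynamics and validating predicted outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaflow)
```

## The measurement problem

Predicting the haemodynamic outcome of aortic valve replacement means
simulating flow in a virtually treated anatomy and claiming that the
simulated field resembles what will actually be measured after surgery.
Such a claim is only testable if both fields — the predicted one and the
post-operative 4D velocity-encoded MRI — are reduced to the *same* scalar
endpoints by the *same* deterministic procedure, and the per-patient pairs
are then compared with a pre-registered statistical protocol. `aortaflow`
is that procedure: a velocity field on a voxel grid plus a triangulated
vessel wall go in, a per-level metric table, flow-pattern grades, wall
shear stress estimates, surface-distance measures and paired statistics
come out.

The package deliberately stops at the field level. Producing the fields —
MRI reconstruction, segmentation, virtual valve insertion, the CFD solve
itself — is upstream and out of scope.

## Flow metrics and their assumptions

**Cross-sections.** A measurement plane is intersected with the wall mesh;
the intersection must be a single closed contour (anything else indicates
the plane misses the vessel or cuts it twice, and is an error, with the
loop count reported). The lumen area is the polygon (shoelace) area of the
contour, and `R_mean = sqrt(A/pi)` is the equivalent-circle radius; both
are therefore mesh-resolution limited rather than lattice limited. Velocity
components are sampled on a regular in-plane lattice (default pitch 0.5 mm)
by trilinear interpolation from voxel centres. Trilinear interpolation
matches the smoothness of velocity-encoded data; samples outside the grid
are errors, never silently zero.

**Secondary flow degree.** `SFD` is the lumen average of the in-plane speed
divided by the lumen average of the absolute through-plane velocity.
Magnitudes are averaged *before* the ratio: averaging vector components
first would cancel any symmetric swirl to zero, contradicting the fact
that strongly helical flow carries nonzero SFD. Values above 2.5 exceed
what is observed even in severe valve disease, so the pipeline flags them
as suspect rather than failing.

**Wall shear stress.** Two estimators are exposed on purpose. `WSS_HP`
(`eta * 4 * V_mean / R_mean`, with dynamic blood viscosity
`eta = 3.5e-3` Pa·s by default) is the idealised fully developed laminar
value; it is insensitive to secondary flow and isolates the effect of
lumen-diameter errors. `WSS_SA` estimates the real tangential wall
gradient: at every wall face the tangential speed is sampled at depths
`d` and `2d` along the inward normal and combined into the one-sided
second-order stencil `(4 v_t(d) - v_t(2d)) / (2d)`, which is exact for a
parabolic profile under no-slip at the wall. The wall sample itself is
deliberately *not* used: at or beyond the wall, voxelised data blend into
signal-free territory and would corrupt the stencil. Two consequences
matter in practice:

- the default probe depth of 1 mm must stay below the lumen radius but
  above ~half the voxel pitch, otherwise both probes interpolate the same
  voxels;
- the wall mesh must be tessellated finely enough that face centroids lie
  on the no-slip surface to within a small fraction of the probe depth. On
  a coarse faceted cylinder (48 circumferential segments at R = 14 mm) the
  centroids sit ~0.03 mm inside the true wall, which biases the Poiseuille
  recovery by ~+4%; at 96 segments the bias is ~0.5% and the estimator
  converges cleanly to the analytic `2 eta v_peak / R` as the voxel pitch
  is refined from 2.5 mm to 0.625 mm.

The inward normal is the face normal flipped towards the mesh's principal
axis — valid for tubular walls, which is the intended domain.

**Rotation grades.** Helicity is graded from the streamline rotation angle:
massless particles are seeded on a circle of radius `R/2` in the entry
section and advected through the steady field by fixed-step 4th-order
Runge-Kutta integration of the velocity *direction* (arclength
parametrisation, step = half the smallest voxel pitch). The signed azimuth
about the local centerline is accumulated unwrapped, and the reported angle
is the median absolute total rotation over seeds that traverse the segment
— the median resists the occasional streamline that hugs the wall. More
than half the seeds exiting early is an error. Grading follows the
rotation convention: `marked` above one full turn (360°), `mild` below it,
and `none` up to a 90° threshold — a strictly zero `none` threshold would
be unattainable under measurement noise, and 90° separates "normal" from
"mildly helical" far from both boundaries. Vorticity reuses the same
machinery about an axis perpendicular to the vessel's plane of curvature.

**Eccentricity grades.** The qualitative criterion — central jet / jet over
one to two thirds of the lumen / rim-only jet — is quantified by two
numbers: the lumen-area fraction `A_f` of the high-velocity region (samples
at or above 70% of the section peak) and the offset `e` of its centroid
from the lumen centroid in units of `R_mean`. `marked` requires a small,
displaced region (`A_f < 1/3` and `e > 0.4`); `none` requires a central one
(`e <= 0.2`); everything else is `mild`. The 0.70 threshold keeps the
high-velocity region of a centred parabolic profile compact (`A_f ≈ 0.3`);
both cutoffs are configurable in `analysis_config()`.

## Boundary conditions

Murray's law distributes a total outflow over branch vessels as
`Q_i ∝ d_i^3`; the exponent is configurable but defaults to the cubic law.
Fractions are computed analytically, so mass balance closes exactly by
construction. Inlet mapping assigns each node of an inlet mesh the
trilinearly interpolated velocity vector and integrates the area-weighted
face-normal flux (mm² × m/s = mL/s); the inlet normal is defined to point
into the domain, and a negative flux warns about flipped normals instead
of failing, since mesh orientation conventions vary.

## Anatomical comparison

Surface distances are vertex-to-triangle (point-to-surface, not
point-to-point nearest vertex), pooled symmetrically by default; the
Hausdorff distance is the maximum over samples. Symmetric pooling is the
conservative reading of a "maximal surface distance". Alignment is rigid —
rotation and translation, no scaling — by point-to-plane ICP: the
least-squares problem is linearised on the local surface normals, so
tangential sliding along facets is free, which avoids the systematic
under-rotation of point-to-point pairing on tessellated surfaces. The
normal equations are solved by minimum-norm SVD because tubular surfaces
have genuinely unobservable motions (an open cylinder can slide along its
axis without changing any point-to-plane residual); those components are
left at zero. Two caveats follow from symmetry, not from the
implementation: rotation about the axis of a circular cylinder is
unidentifiable in principle, so known-transform recovery is exercised on
elliptical tubes; and alignment is guarded never to worsen the mean
distance of the pair it is given.

## The paired validation protocol

All comparisons are `predicted - observed`, in the t-test and in
Bland-Altman alike. The protocol per metric is: Lilliefors-corrected
Kolmogorov-Smirnov normality screen on the differences (the correction is
needed because the normal parameters are estimated from the sample; a
plain-KS switch is provided for comparability with software that ignores
this); paired t-test with `n - 1` degrees of freedom; regression through
the origin `slope = sum(xy)/sum(x^2)`; Bland-Altman bias with
`bias ± 1.96 sd` limits (1.96 is a fixed constant, matching the reporting
convention, not a t quantile); and a Friedman test on ordinal grade tables
(none = 0, mild = 1, marked = 2) using within-subject midranks with the
tie-corrected chi-square statistic on `k - 1` degrees of freedom. The
two-method case is retained although the statistic then degenerates to a
sign-test-like form, because validation compares exactly two methods. An
exact permutation reference (`friedman_exact_p()`) enumerates all
within-subject orderings for small tables and anchors the implementation
in tests. The familywise level is Bonferroni-adjusted; with the six
validation endpoints (peak velocity, helicity, vorticity, eccentricity,
WSS, SFD) and `alpha = 0.05` the threshold is 0.0083.

Degenerate inputs are handled explicitly rather than propagated: identical
pairs give `t = 0, p = 1`; a constant nonzero difference gives `p = 0`
with a `degenerate` flag; zero-variance samples are rejected by the
normality screen; incomplete pairs and subjects missing a method are
dropped with a logged count. For the no-intercept regression the reported
R² is `1 - SS_res / SS_tot` with `SS_tot` about the mean of the response —
the convention of common statistical software; no-intercept R² conventions
differ, which is why a printed R² is treated as convention-dependent
rather than a recoverable quantity.

## What the synthetic phantoms do and do not emulate

The generators produce the three analytic families the metrics have closed
forms for: Poiseuille flow (truth: `WSS = 2 eta v_peak / R`, `SFD = 0`,
lumen mean `v_peak/2`), plug flow with solid-body swirl (truth:
`SFD = 2 omega R / (3 v)`, helical streamlines at `omega / v` radians per
metre), and eccentric jets whose analytic area fraction and centroid
offset realise each eccentricity grade. The jet sub-disk is clipped to the
lumen — a rim-hugging jet protrudes past the wall by construction, and the
clipped (lens-formula) area is the meaningful one. Measurement noise is
additive i.i.d. Gaussian per velocity component inside the lumen; this is
a simplification (velocity images are phase-derived, so no Rician
magnitude noise), and since the acquisition noise level is not known from
the study conditions it is a free parameter rather than a calibrated one.
The noise induces a predictable SFD floor: the in-plane noise magnitude is
Rayleigh, so a noiseless-axial section acquires
`SFD ≈ sigma * sqrt(pi/2) / (v_peak/2)`, which the tests verify by Monte
Carlo. Phantoms are straight, single-phase and steady: no curvature, no
pulsatility (peak systole only), no Womersley profiles. Passing tests
therefore demonstrate correctness of the estimators on smooth tubular
flow, not robustness to arch curvature, turbulence or acquisition
artefacts. All generators take mandatory seeds and hold no global state;
regeneration is bit-identical.

## Numerical choices and problem sizes

Coordinates are physical millimetres, velocities m/s, right-handed axes,
0-based voxel indices with voxel (0,0,0) centred at the grid origin.
Plane-mesh contour chaining keys intersection points by the crossed mesh
edge, so loop detection needs no coordinate tolerance. Lattice membership
uses strict point-in-polygon tests; lumen membership of the generators is
a strict voxel-centre-inside test, avoiding partial-volume ambiguity in
the oracles. Streamline integration uses half the voxel pitch; ICP stops
when the mean distance changes by less than 1e-4 mm, capped at 50
iterations, on a 500-vertex subsample. The test and acceptance runs use
phantoms of 27-67 voxels per axis (up to ~0.4 M voxels at the finest
0.625 mm pitch), walls of 1-5 thousand faces, 10-subject cohorts for the
protocol examples, 10^4 replicates for the type-I-error calibration and
200 seeds per coefficient for slope recovery — sizes chosen so the full
suite completes in a few minutes while every tolerance is dominated by
discretisation, not by sampling noise.

## Known limitations

- Vessels are assumed tubular: the inward-normal heuristic, the centerline
  refinement and the vorticity axis all rely on a well-defined principal
  axis, and fail on branching or strongly curved geometry.
- The centerline tool is a section-centroid refinement, not a
  skeletonisation; strongly curved vessels need an externally supplied
  centerline.
- `WSS_SA` inherits the resolution limits of near-wall interpolation;
  voxel pitches coarser than the probe depth underestimate gradients.
- Region-of-interest restriction for surface comparison (valve plane, arch
  start) is the caller's responsibility; the package does not detect
  anatomy.
- The Friedman p-value is asymptotic; for the cohort sizes used in
  validation studies the exact permutation reference is the more faithful
  quantity and is provided alongside.
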