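---
title: "Virtual patch angioplasty: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual patch angioplasty: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vpatch simulates the patch repair of a stenosed great artery — the main
pulmonary artery of a child with Tetralogy of Fallot is the dimensioning
case — from the surgeon's point of view: cut the narrowed vessel open,
stretch the slit, sew in a patch, and predict what the reconstruction looks
like and how it is loaded once the heart is back on circulation.  This
vignette records the models behind each stage, the tunable parameters, and
the design decisions taken where several formulations were defensible.

## The vessel and its stenosis

The vessel is an axisymmetric tube: 18 mm inner diameter, 1 mm uniform wall,
100 mm long, matching published reference dimensions for a 9-year-old main
pulmonary artery.  The stenosis removes a fraction `s` of the lumen *area*
at the throat; the lumen radius follows
`r(z) = r0 * sqrt(1 - s * w(z))` with `w` a raised-cosine bump over the
stenosed span (50 mm by default), so the throat area is exactly `(1 - s)`
times the inlet area.  The axial profile of a real stenosis is not uniquely
defined by a single percentage; the raised cosine is smooth, symmetric and
matches the intent of a "symmetric stenosis, the clinically most common
case".  Eccentric stenoses are out of scope.

The wall is represented by a single mid-surface shell at
`r_lumen + t/2` with the thickness carried as an element attribute.  The
default generator edge length is 0.5 mm; the full-case studies in the tests
and in `scripts/acceptance.R` run at 2.5 mm (about 1 100 nodes, 2 100
shell elements per vessel), the resolution at which a complete ten-stage
case solves in a few minutes on one CPU.  All comparisons against the
reference study are therefore *scaled-down* reproductions; the closed-form
solver oracles (below) are resolution-controlled instead.

## Materials

All materials are isotropic linear elastic, the standard idealization for
these patch comparisons over the operating strain range; the library holds
the biaxially measured constants (porcine xenopericardium, fresh human
pericardium, PTFE, Dacron) plus the native artery wall
(E = 0.75 MPa, nu = 0.45, t = 1 mm).  `fit_linear_elastic()` reproduces the
property-extraction step: a least-squares fit of the plane-stress model to
biaxial stress–strain records inside a strain window (default 0–15%, the
arterial operating range).  The model is linear in
`C1 = E/(1-nu^2), C2 = nu*C1`, so the fit is an ordinary least-squares
solve, mapped back to `(E, nu)`.  Strictly proportional (equibiaxial)
loading paths leave only `E/(1-nu)` identifiable; the synthetic protocol
therefore phase-shifts the two sinusoidal strain axes (20% peak strain,
matching the physical test protocol) and the fit warns on rank-deficient
paths instead of returning spurious constants.

## The shell solver

The solver is a quasi-static, geometrically nonlinear thin-shell FEM built
for this package:

* **Element.** Flat 3-node shell: constant-strain membrane plus a
  discrete-Kirchhoff (DKT) bending triangle, 6 DOF per node, with a small
  drilling stiffness (1e-6 of the element diagonal) stabilizing the
  in-plane rotation.  The DKT curvature field passes the constant-curvature
  patch test to machine precision.
* **Kinematics.** An element-attached corotational frame separates the
  (large) rigid motion from the (small) deformational part; nodal triads
  are updated multiplicatively.  The internal force is the exact gradient
  of the corotational strain energy, including the consistent spin
  projector; we verified `f = dE/du` by central finite differences to
  1e-5 relative.
* **Tangent.** The element tangent is assembled by forward finite
  differencing of that exact internal force (the local element matrix is
  reference-constant, so a force evaluation is cheap); this captures all
  geometric-stiffness terms and keeps Newton quadratic.  The
  follower-pressure load stiffness is differenced the same way and kept
  unsymmetric.
* **Loads.** Pressure follows the deformed mid-surface normal (lumped per
  element); slit-edge tractions follow the deformed lip direction, with a
  finite-difference Jacobian of the traction field added to the tangent.
* **Solution.** Incremental loading with Newton iterations, relative
  residual tolerance 1e-6, direct sparse LU solves, automatic increment
  halving to 1/64 of the initial step; a trust region caps translation
  steps at 5 mm and rotation steps at 0.3 rad, backtracking accepts
  non-monotone residuals up to a factor 10 (Newton legitimately overshoots
  entering its quadratic basin), and adaptive Levenberg–Marquardt damping
  handles indefinite tangents near wrinkling.
* **Snap-through.** Between 25 and 45 mmHg the re-pressurized
  reconstruction passes a genuine limit point (the formerly stenosed arch
  next to the suture line pops outward).  Load stepping cannot cross a
  limit point, so the ramp falls back to grounded stabilization springs
  (1e-2 of the tangent diagonal, re-anchored and ramped 1e-2 → 0) that
  carry the structure onto the stable post-snap branch; the final solve is
  spring-free, so the reported equilibrium is unmodified.

Boundary conditions follow the clinical setup: the ring near the outflow
tract is fully fixed, the other ring keeps its radial and circumferential
position but slides axially and rotates freely.  Fully clamping both ends
is known to exaggerate patch deformation.

The solver is verified against closed forms: pressurized-cylinder hoop
stress `p*r/t` and radial expansion `p*r^2/(E*t)` within 0.5% at the test
resolution, a simply supported plate against the Kirchhoff series solution
within 1%, reaction/load balance to 1e-9, and linearity of the response at
small loads.

## The virtual surgery sequence

1. **Residual stress.** Arterial residual stress is represented by the
   pressure-equivalent technique: the intact unloaded vessel is inflated to
   5 mmHg and the resulting per-element membrane stress field is embedded
   as initial stress, after which the external pressure is removed — the
   intra-operative artery (cardiopulmonary bypass, zero lumen pressure)
   carries residual stress only.  Re-solving the slit mesh releases it: the
   lips separate by a few micrometres, the "slight opening" of a real
   arteriotomy.
2. **Incision.** The straight (or 5-degree helical) cut is snapped to mesh
   vertices, centered on the stenosis, with its along-surface length
   matched to the requested cut length as closely as the grid permits.
   Cutting duplicates the interior path nodes and re-wires one side of each
   node fan, producing two coincident free edges that share the tip nodes:
   a zero-gap slit, topology otherwise untouched.
3. **Slit stretch.** The spec'd intra-operative parameter is the opening
   width (16 mm in the reference cases).  Two control modes exist.  The
   default mimics the surgeon directly: the lip nodes over the central half
   of the slit form a retractor jaw whose opening displacement is
   prescribed in equilibrium steps until the mid-slit width (where the
   patch must clear the throat) reaches the target; displacement control
   traverses the limit points this shell passes through, and the jaw
   reaction is reported as the equivalent edge traction.  The alternative
   mode ramps a uniform distributed follower traction normal to the cut
   faces with a secant loop on its magnitude; it matches the
   traction-boundary-condition description literally but cannot pass limit
   points and saturates below wide openings, so it is kept for moderate
   gaps and for the monotonicity properties.  Under uniform traction the
   throat (smallest radius, stiffest arch) opens *least* — incompatible
   with a 16 mm clearance at the throat — which is why the
   displacement-controlled jaw is the default.  The jaw span (half the
   slit) is the one free parameter; it was fixed once, on the argument
   that stay sutures hold the middle half of an arteriotomy open, and it
   reproduces the reference patch-area trend across cut lengths.
4. **Tangent patch.** For every pair of corresponding lip nodes a cubic
   Hermite cross-curve leaves the left lip tangent to the artery surface
   and arrives tangent at the right lip (tangent magnitude = chord length,
   which reproduces circular continuation in the small-angle limit).
   Sampling along each cross-curve is graded toward the lips (a
   uniform/cosine blend) so the discrete surface actually carries the end
   tangency; the rows are ladder-triangulated and the interior is
   smoothed with ten Taubin passes (lambda 0.5 / mu −0.53, boundary and
   its first interior ring fixed) — the discrete analogue of a
   curvature-continuous "tangent patch", without the local tail bulges a
   raw fill leaves.  Patch element size follows the artery mesh.
5. **Suture.** Patch boundary nodes *are* the slit-edge nodes: a bonded
   tie with shared degrees of freedom, tagged `suture_line`.  The patch is
   born stress-free in its as-built shape (each element stores its own
   reference configuration and reference nodal triads, so artery elements
   keep their unloaded reference while patch elements use the as-built
   one).  Sheet-bending prestress of the raw patch material is neglected.
6. **Post-operative pressurization.** The jaw constraints are released and
   the lumen pressure is ramped to 25 (or 45) mmHg as a follower load.
   Whether the surgeon's pull is removed before or after pressurization is
   not observable in the final state (elastic equilibria are
   path-independent); we release it at suturing.

## Performance indices

The deformed tube is sliced by planes normal to a running centerline
estimate (section contours chained through the mesh edges they cross,
centroids re-fit with a smoothing spline, two to five passes).  Contour
areas are corrected from mid-surface to lumen by an inward half-thickness
offset (`A - P*t/2 + pi*t^2/4`, mean local thickness).  Local stenosis is
`100*(1 - A(s)/A_ref)` with the reference the largest cross-section of
the *native* (non-patched) vessel in the post-operative state: sections
crossing a bulging patch can then dip below zero (dilation), the
behavior the reference's area-recovery curves display; on an unpatched
vessel the reference is simply the profile maximum.  The throat is the
sample of maximum local stenosis, and the centerline
offset (tortuosity) is the distance of the post-op centroid from the
original straight axis at the throat.  Stress summaries are mid-surface
plane-stress von Mises values per element region; the suture-line stress
jump is the largest per-node difference between adjacent patch and artery
element maxima.  The "stenosis recovery ratio" quoted for the material
cases in the reference has no printed formula consistent with the other
numbers and is deliberately not computed.

## Reduced-order hemodynamics

The full 3-D CFD of the reference is out of scope; the package provides a
comparative estimator only: the cross-section-averaged Reynolds profile
`Re(s) = rho*Q*D_eq/(mu*A)` (blood at 1060 kg/m^3 and 3.5 mPa s, 4 L/min
mean flow — the density and viscosity are a reconstruction, chosen as the
standard large-vessel values, and they reproduce the published peak
Reynolds number of the 70% pre-operative vessel), and a pressure-drop
estimate summing an integrated Poiseuille term and a Young–Tsai-type
turbulent constriction loss (`Kt = 1.52`).  Use these to rank
configurations, never as absolute drops.

## What the synthetic data do and do not show

The generator produces idealized axisymmetric vessels with linear-elastic
walls and a smooth stenosis; passing tests on them demonstrates the
internal consistency of the pipeline and its agreement with closed forms
and with the reference parametric study's trends — not fidelity to any
individual patient anatomy, hyperelastic/anisotropic wall behavior,
suture-by-suture mechanics, fluid–structure interaction, or absolute CFD
pressure fields.  Mesh resolution is the main scaled-down compromise: at
2.5 mm the residual-stenosis figures carry a few percentage points of
discretization bias relative to the sub-millimetre reference solutions,
which is inside the tolerance bands used in the tests.

## Known limitations

* Load-controlled uniform edge traction cannot reach wide openings (limit
  points); the retractor mode is the supported route to a 16 mm stretch.
* The centerline slicer requires a single lumen contour per station; a
  pinched lumen raises an error naming the axial location.
* Oblique incisions assume the generator's structured mesh for path
  snapping; arbitrary imported surfaces are only supported for straight
  pipelines built by hand.
* Stresses are mid-surface membrane values; bending-fiber stresses are
  available in `fem_state()` but are not used in the reported indices.
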