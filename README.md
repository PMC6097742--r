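# vpatch

Pre-surgical planning of arterial patch reconstruction, at desk scale.

Repairing a stenosed great artery — the main pulmonary artery in Tetralogy
of Fallot surgery is the dimensioning case — means cutting the narrowed
vessel open, stretching the slit, and sewing in a patch of PTFE, Dacron or
pericardium.  Which cut length, cut shape, patch material and
post-operative pressure give the best lumen recovery at acceptable wall
stress?  `vpatch` lets you run that comparison *in silico*: it generates
parametric stenosed-vessel shell meshes, performs the virtual surgery
sequence (pressure-equivalent residual stress, incision, controlled gap
opening, tangent-patch synthesis, bonded suturing, post-operative
pressurization) with a corotational triangular thin-shell finite-element
solver written for this package, and evaluates the standard performance
indices.

The core models, in the field's notation:

* **Geometry.** Axisymmetric tube, lumen radius
  `r(z) = r0 sqrt(1 - s w(z))` with `w` a raised-cosine bump, so `s` is
  the fractional *area* stenosis at the throat (defaults: D = 18 mm,
  t = 1 mm, 70% or 80% stenosis over 50 mm).
* **Wall and patch mechanics.** Isotropic linear-elastic thin shells
  (CST membrane + discrete-Kirchhoff bending, corotational kinematics,
  follower pressure), quasi-static Newton continuation with consistent
  finite-difference tangents.  Residual stress enters by the
  pressure-equivalent technique (5 mmHg inflation stored as initial
  stress).
* **Materials.** Biaxially measured constants for the surgical materials,
  and `fit_linear_elastic()` to extract `(E, nu)` from planar biaxial
  records by least squares on the plane-stress model
  `sigma_x = E/(1-nu^2) (eps_x + nu eps_y)`.
* **Indices.** Centerline extraction by iterative normal slicing; local
  stenosis `100 (1 - A(s)/max A)`; throat residual stenosis; centerline
  offset (tortuosity); regional von Mises summaries; suture-line stress
  jump from material mismatch.
* **Hemodynamics (reduced order).** `Re(s) = rho Q D_eq / (mu A)` and a
  Poiseuille + Young–Tsai pressure-drop estimator — comparative figures,
  not CFD.

## A worked example

The baseline repair of the reference study: 70% stenosis, 50 mm straight
cut, 16 mm slit stretch, PTFE patch, 25 mmHg post-operative pressure.

```r
library(vpatch)
cfg <- read_scenario(cases_table1())$Baseline
rep <- run_case(cfg)
print(rep)
#> case Baseline: patch 626 mm^2, post-op stenosis 22.2%,
#> max artery 178 kPa, max patch 54 kPa, offset 6.5 mm
```

Reading the numbers: the tangent patch needed about 6.3 cm^2 of PTFE; the
worst residual narrowing along the reconstructed centerline is ~22% of
the largest native post-operative cross-section (down from 70%
pre-operatively); peak wall stress sits on the artery next to the suture
line, an order of magnitude below typical arterial failure stress; and
the repaired conduit bows ~6.5 mm off the original vessel axis at the
throat.  `run_matrix()`
runs all ten bundled scenarios (`inst/extdata/cases_table1.yaml`) and
tabulates the same columns per case; a thin command-line wrapper lives in
`inst/cli/vpatch.R` (`run`, `matrix`, `fit-material`).

Individual stages are ordinary functions — `build_stenosed_tube()`,
`trace_incision()`, `cut_slit()`, `open_gap()`,
`generate_tangent_patch()`, `suture()`, `solve_stage()`,
`extract_centerline()` — so non-standard pipelines (imported STL surfaces,
custom materials, partial stages) compose directly; meshes and fields
export to STL/PLY/VTK.

See `vignettes/patch-planning-methods.Rmd` for the models, solver
formulation, parameter choices and limitations.

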