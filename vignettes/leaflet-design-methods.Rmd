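---
title: "Methods: parametric leaflet design, membrane simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parametric leaflet design, membrane simulation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvegen)
```

`valvegen` evaluates candidate leaflet geometries for bioprosthetic heart
valves through a generate → simulate → analyze pipeline.  This vignette is
the package's account of the underlying models, the choices that were
genuinely open when it was designed, and what its verification does and
does not establish.

## The parametric surface

A single leaflet of a tri-leaflet valve is described by six quantities:
height `H1` (mm), free-edge deviation `φ` (degrees), dome sag `R`
(percent), prosthesis radius `Rin` (mm), thickness `T` (mm), and the
angular span of one leaflet `Sec` (degrees, default 119 — commercial
designs leave a small commissural gap in the 120° slot).

Only the parameter list is standardised in the field; the surface
equations are this package's own construction, chosen to be smooth,
single-valued in the circumferential parameter, and to reproduce the
qualitative anatomy:

* **Attachment scallop** (`u = 0`, pinned in the simulation): on the
  cylinder `r = Rin`, with height
  `z_att(θ) = H1·(1 − cos(πθ/(Sec/2)))/2` — low at the belly, rising to
  `H1` at the commissures.
* **Free edge** (`u = 1`): in the closed valve the three free edges meet
  along the coaptation "Y", so the free-edge point at parameter `θ` lies
  on the sector-boundary radius (polar angle `±Sec/2`) at distance
  `r = Rin·|θ|/(Sec/2)` from the axis, with height
  `z_free = H1 − tan(φ)·(Rin − r)`.  Positive `φ` therefore drops the
  middle of the free edge toward the ventricle; negative `φ` raises it.
* **Interior**: a linear Cartesian blend between the two curves at equal
  parameter, plus an axial dome-sag bubble
  `−(R/100)·0.25·Rin·sin(πu)·cos(πθ/Sec)` (maximum depth `0.25·Rin` at
  `R = 100 %`, vanishing at all edges).

This placement of the free edge is what makes the closed leaflet cover
exactly its third of the orifice in projection — the property the
degree-of-opening metric is anchored to, and one of the package's
acceptance checks (closure within 1.5 % at raster resolution).

The attachment and free edge meet at the commissure tips, so the two end
columns of the structured `(nu × ntheta)` grid collapse to single points.
They are welded into one node each, which keeps every triangle area
positive and every edge manifold; the mesh therefore has
`nu·(ntheta − 2) + 2` nodes and `2·(nu − 1)·(ntheta − 2)` triangles.
Retaining the duplicated grid columns instead would create `2·(nu − 1)`
zero-area slivers, which break both mesh validity and the explicit
time-step estimate.  `ntheta` must be odd so the leaflet centreline is
sampled.

## Tissue model

Uniaxial tensile curves of (xeno)pericardium vary strongly between
samples, so the standard practice of averaging a sample set into one law
is followed: all points of all curves are pooled and a cubic polynomial
without constant term,
`σ(ε) = c1·ε + c2·ε² + c3·ε³`, is fitted by least squares — equivalent to
solving the normal equations of the pooled design matrix, which the test
suite verifies to 1e-8 against a direct solve.  Pooling (rather than
averaging per-curve coefficients) weights each measured point equally; the
origin constraint makes `σ(0) = 0`, which any solid solver needs.  The fit
quality is reported as R² on the pooled points (centred form).  Beyond the
largest fitted strain the law continues linearly with the end tangent — a
documented clamp that keeps extrapolation finite if an element is
over-stretched.

Measured pericardium data are not shipped.  A seeded generator
(`synth_tensile_curves()`) emulates a tensile experiment: truth cubic on a
jittered strain grid, per-sample lognormal stiffness factor (SD(log) 0.1,
the natural inter-sample variability), and Gaussian stress noise
(default 0.05 MPa).  The built-in default law uses coefficients
`(1, 5, 150)` MPa on `ε ∈ [0, 0.4]`: a compliant toe region that stiffens
to ≈11 MPa near 40 % strain, i.e. reaching the 11.6 MPa ultimate strength
of treated pericardium at the end of its range.  Density 1.1·10⁻⁹
tonne/mm³ and Poisson ratio 0.45 are typical soft-tissue values.  The
generator reproduces inter-sample scatter and noise, but not anisotropy,
hysteresis or strain-rate effects — so passing parameter-recovery tests
says the *averaging machinery* is correct, not that any real tissue is
captured.

## Membrane finite elements

The leaflet is thin (`T ≤ 1 mm` against `Rin ≥ 7.5 mm`), so bending
stiffness is neglected: constant-strain triangles carry in-plane
Green–Lagrange strain in a total-Lagrangian setting.  The in-plane
response is an isotropic plane-stress *secant* law derived from the fitted
uniaxial curve: at equivalent Green strain
`ε_eq = sqrt(E11² − E11·E22 + E22² + 3·E12²)` the modulus is
`E(ε_eq) = σ(ε_eq)/ε_eq` (limit `c1` at zero strain), applied through the
usual plane-stress stiffness with the material's Poisson ratio.  The
constitutive form used in commercial leaflet analyses is generally not
disclosed; this choice reproduces the fitted uniaxial curve exactly in a
single-element patch test (one of the acceptance checks) and is cheap and
robust at the moderate strains (≲15 %) the opening phase produces.

Loading is the net (ventricular − aortic) pressure difference applied as a
follower load on the current element normals — for a membrane midsurface
this is mechanically equivalent to loading the two faces separately.  The
waveform is parametric (smoothstep by default, peak 30 mmHg over 0.2 s,
held afterwards) because published pressure traces for the opening phase
are not tabulated; results that depend on the absolute pressure level are
therefore qualitative.  Quantities are converted with
1 mmHg = 1.33322·10⁻⁴ MPa; the internal unit system is mm–MPa–N–tonne–s.

Quasi-static opening is computed by explicit central-difference dynamics
with mass scaling and mass-proportional damping — the standard engineering
route for opening simulations:

* time step `dt = dt_scale · l_min / c`, `c = sqrt(E_max/(ρ_eff(1−ν²)))`,
  with `E_max` the largest tangent modulus over the fitted range and
  `l_min` the smallest `2·area/longest-edge`; `dt_scale = 0.8`;
* `mass_scaling = 400` and `damping_alpha = 400 s⁻¹` by default.  These
  were chosen once so that the default opening run *settles*: the
  kinetic/strain-energy ratio at the end of the 0.2 s window is below
  10⁻⁵ for the worked 19-mm design, i.e. the reported state is the static
  equilibrium at peak load rather than a snapshot of a transient.  Every
  run reports the ratio and warns above 0.10;
* the damping update is implicit (`v ← (v + dt·a)/(1 + α·dt)`), which is
  unconditionally stable in the damping term;
* attachment nodes are pinned exactly (velocities zeroed), divergence
  aborts with the step number, and degenerate elements are reported by
  index rather than clamped.

Verification: a single-element uniaxial patch test (exact against the
fitted law), rigid-motion invariance of the internal forces (machine
precision, a property of Green strain), zero-load rest preservation, an
energy inequality (external work ≥ kinetic + strain energy, damping
dissipating the difference), and the uniformly loaded flat circular
membrane against the classical closed-form centre deflection
`w0 = 0.662·a·(p·a/(E·T))^{1/3}` — reproduced within 10 %, with
mesh-refinement changes below 3 % (the residual offset is the
Poisson-ratio dependence of the closed-form coefficient, quoted for
ν ≈ 0.3 but run here at ν = 0.45).

## Evaluation metrics

Von Mises stress is the plane-stress form
`sqrt(σ11² − σ11σ22 + σ22² + 3σ12²)` of the element-local in-plane
stresses; the field is summarised by mean, maximum and *population* SD
(the field is the whole population of elements, not a sample).

The degree of opening compares the deformed leaflet's XY-projection
against the leaflet's share of the orifice:
`DO = S/(π·Rin²/3)·100 %` with `S` the reference area minus the area the
leaflet still covers.  The covered area is the union of projected
triangles clipped to the disc `r ≤ Rin`, rasterised at 0.05 mm/pixel —
a tolerance-controlled choice that is simpler and more robust than exact
polygon union; at this resolution the raster error is well below the
1.5 % closure tolerance.  `S` is clamped to `[0, π·Rin²/3]`, which also
answers the edge case of a deformed leaflet leaving its own sector (DO
cannot exceed 100 %).

The loss index combines the two criteria into one "the less, the better"
scalar.  The normalised Euclidean form

`LI = sqrt( ((100 − DO)/100)² + (σ_max/σ_lim)² )`, `σ_lim = 11.6 MPa`,

was adopted because it satisfies all the stated anchors of the metric: 0
at full opening with zero stress, monotone in both arguments, and above 1
whenever the peak stress exceeds the material strength.  It reproduces the
published worked values 0.19 (from DO = 84.48 %, σ_max = 1.21 MPa) and
0.20 (88.12 %, 1.87 MPa) exactly at two decimals.  The third published
value (0.24 from 88.28 %, 3.62 MPa) is not reproduced by this — or any
normalisation tried — and evaluates to 0.33 here; it is left as a
documented discrepancy rather than forced.

## Design-space exploration

Designs are sampled independently and uniformly per parameter over
`H1 ∈ [10, 25]` mm, `φ ∈ [−30, 30]°`, `R ∈ [0, 100] %`,
`Rin ∈ [7.5, 20]` mm, `T ∈ [0.1, 1]` mm with `Sec` fixed at 119°.
Whether the original large-batch study gridded or randomised its 1517
geometries is not stated; uniform sampling is the documented choice here
(`lhs`-style stratification could be added, but uniform draws are what
the distributional tests assume).  Each design is an independent pure
function of its parameters, so batch results are deterministic for a
given seed and independent of evaluation order and worker count; failures
are recorded per design (`status = "diverged"`), never dropped.

Filtering keeps designs with `DO > 80 %` and peak stress below a ceiling —
11.6 MPa (the ultimate strength) or the conservative 4 MPa margin, which
sits 65 % below it.  Quartile groups are rank-based (ties broken by
order), which guarantees the top group's mean dominates the overall mean.
Selection for a prosthesis size takes the minimum-LI design within a
±0.5 mm window on `Rin` (the diameter-to-radius mapping of commercial
sizing is not standardised, so a window on the printed radii is used),
with ties broken by higher DO, then lower peak stress, then design id.

Published headline batch statistics (1517 designs, 278 survivors under
the 80 %/4 MPa screen, DO = 71.97 ± 15.91 %) depend on an unavailable
measured material curve and undisclosed solver settings, and are not
reproduction targets.  What the package asserts instead — and its test
suite measures on a 30-design batch at coarse resolution (`nu = 9`,
`ntheta = 17`, seed 7; about 2–3 minutes on one core) — are the two
monotone trends those statistics imply: thicker leaflets open less
(Spearman ρ(T, DO) < 0), and wider-opening designs carry higher peak
stress (ρ(σ_max, DO) > 0).  The problem sizes used throughout the tests
(`nu × ntheta` up to 11 × 21, 30-design batches, one disc benchmark at
two resolutions) were chosen as the coarsest meshes whose verification
metrics are resolution-stable.

## Known limitations

* One leaflet, opening phase only: no diastolic closure, no
  leaflet-to-leaflet contact, no coaptation area or contact stress.
* No fluid–structure interaction — structural follower pressure only.
* Membrane kinematics: no bending stiffness, hence no wrinkling
  resolution; compressive in-plane states are carried elastically rather
  than through a wrinkling model.
* Isotropic secant law: no anisotropy, viscoelasticity or hysteresis;
  conversion to true stress is not attempted.
* Absolute DO and stress magnitudes depend on the synthetic material and
  the assumed 30 mmHg gradient; rankings and trends are the intended
  outputs.
* The exact surface equations of the original generator are unpublished;
  absolute geometric agreement with meshes from other implementations
  cannot be asserted, only the documented equations above.
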