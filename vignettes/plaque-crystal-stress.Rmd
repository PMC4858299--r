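---
title: "Modelling cholesterol-crystal stress on the fibrous cap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cholesterol-crystal stress on the fibrous cap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capstress)
```

## The model

`capstress` solves static plane-strain linear elasticity on an idealized
cross-section of an atherosclerotic coronary artery and reports the peak
circumferential stress (PCS) on the fibrous cap — the maximum hoop stress
σ_θθ over cap recovery points — under luminal blood pressure and the
expansion of plate-like cholesterol crystals lodged at the abluminal face of
the cap. Plane strain (ε_z = 0) is appropriate for a long prismatic vessel;
the analysis is geometrically and materially linear, so every load case
decomposes by superposition.

### Geometry reconstruction

The cross-section is rebuilt from four primary morphometrics: lumen area
(5.77 mm²), cap thickness (0.091 mm), necrotic-core arc (84.65°) and
core area (2.22 mm²). Only concentric, annular-sector shapes are
reconstructible from arc/area/thickness numbers alone, so:

* the lumen is a circle of radius `sqrt(lumen_area / π)` = 1.3553 mm;
* the core is an annular sector starting one cap thickness abluminal of the
  lumen; its outer radius solves the sector-area equation in closed form;
* the remaining annulus between lumen and wall is fibrous plaque (the cap is
  the plaque layer between lumen and core and shares its material);
* the outer (EEM) radius is chosen so the area stenosis
  `1 − lumen_area / (π r_out²)` equals 70.53%. The quoted relative core
  area and thickness are mutually inconsistent with the primary parameters
  under any single standard definition, so they are reported back as
  diagnostics by `derive_geometry()`, never imposed. A `wall_thickness`
  override replaces the stenosis closure when the media+adventitia thickness
  is known; by default it comes out at 0.239 mm.

### Materials

Artery and plaque are transversely isotropic about the radial axis
(plane of isotropy θ–z). The six given constants are completed by compliance
symmetry: ν_θr = ν_rθ·E_θ/E_r, ν_rz = ν_rθ, ν_zθ = ν_θz with E_z = E_θ.
`plane_strain_D()` builds the 3×3 normal compliance in (r, θ, z), verifies
positive definiteness, inverts, and condenses with ε_z = 0; the same row
recovers σ_zz from the in-plane strains. The core (1 kPa, ν 0.49) and
crystal (100 kPa, ν 0.49) are isotropic through the identical code path, and
a degenerate transversely isotropic material reproduces the isotropic matrix
exactly (this is a unit test).

### Discretization

The half model (symmetry axis through the cap center) is a structured mesh
of 8-node serendipity quadrilaterals on polar blocks: 2 radial layers in the
cap, 6 through the core annulus, 3 through the wall, and ~1.7° angular
spacing with a break line at the core-arc end, giving 1188 elements at the
default refinement (a `refinement` multiplier scales all counts). Midside
nodes lie on the polar mid-arcs, so curved boundaries are quadratic arcs.
Element stiffness uses 3×3 Gauss quadrature, rotating the local (r, θ)
constitutive matrix to Cartesian axes at every quadrature point. A crystal
is a band one element thick (the crystal thickness, 3 µm) and
⌈length/element-width⌉ elements long carved into the top of the cap; all
crystals in one mesh share that slot layer.

Boundary conditions: u_y = 0 on every symmetry-line node implements "radial
motion only" on the centre line. That constraint leaves one rigid mode — the
translation along the symmetry axis — so a single u_x anchor is added at the
outer wall. Every admissible load on the half model (pressure on the half
lumen, self-equilibrated eigenstrains) has zero axial resultant, so the
anchor reaction vanishes (asserted to 1e-8 in the tests) and stresses are
unaffected. Luminal pressure becomes work-equivalent nodal loads on the
quadratic boundary edges of the undeformed configuration.

The system is solved by sparse Cholesky factorization (deterministic,
fixed ordering); the relative residual is checked and must stay below
1e-10 in every scenario.

### Stress recovery and the PCS search domain

Stresses are evaluated at the 3×3 Gauss points, extrapolated to element
nodes by the standard quadratic Gauss-point extrapolation (exact for the
quadratic stress variation the element can represent), averaged over
elements sharing the node *within each material region separately* — so the
cap/crystal and cap/core interfaces are never smeared — and finally rotated
into cylindrical components at the node. On the pressurized thick-walled
cylinder benchmark this recovery reproduces the closed-form hoop stress at
the loaded face to 0.4% at the default density, converging monotonically
under refinement.

PCS is searched over plaque-region recovery points radially between the
lumen surface and the core interface and angularly within the half core arc
plus one element margin; points interior to crystal elements are excluded
but the cap/crystal interface (recovered from the cap side) is included.

### Crystal loading

Growth of the total crystal thickness by *d* is a stress-free eigenstrain
ε* = d/thickness aligned with the local radial direction, applied through
the crystal's own stiffness: equivalent nodal forces ∫ Bᵀ D ε*. Free
expansion then reproduces exactly *d* of thickness increase (a unit test on
a single unconstrained element), the surrounding tissue's compliance sets
the actual displacement, and the load is exactly proportional to *d*, which
is what makes PCS affine in *d* wherever the arg-max node does not move.

## What the model does and does not reproduce

Two structural facts dominate the results, and both are worth making
explicit because they bound what any reconstruction from the printed
parameters can achieve.

**The shoulder corner is singular.** The annular-sector core ends in a
bi-material corner at the shoulder: stiff plaque (E_θ = 1000 kPa) wraps a
90° wedge of 1-kPa core. Linear elasticity makes σ_θθ unbounded there, so
the recovered corner value grows without limit under refinement (411 → 509
→ 580 kPa over refinements 1–3 for the crystal-free control). The *location*
of the control PCS — the cap shoulder — is robust and reproduces the
expected behaviour; its magnitude at the default density (411.4 kPa at
~1200 elements) is a sampling-scale statement, roughly 49% above the
reference value this package aims to match, which presumably reflects a
smoother (e.g. tapered-tip) core contour that the printed parameters do not
encode. The absolute PCS targets inherit this gap.

**A micron-scale push through a 100-kPa crystal is a few-kPa load.** The
crystal can exert at most its constrained eigenstrain stress,
σ ≈ C·(d/t) with C ≈ 1.7 MPa at d = 2 µm — but only against a rigid
support. Against the cap's bending compliance k (deflection per unit
interface traction over the 269 µm footprint), the interface traction is
σ = C·ε*/(1 + C·k), and C·k ≈ 130 here, so the push saturates near 9 kPa
and the local hoop-stress gain is ~2 kPa per µm of expansion. Consequently a
2 µm expansion changes PCS by single-digit kPa (and slightly *unloads* the
shoulder concentration), so the large reported percent increases at 2 µm,
the shoulder>halfway>center ordering at 2 µm, and collocation of the PCS
with halfway/center crystals cannot emerge from this load model; they would
require three orders of magnitude more push. The saturation also explains
why the crystal's Young's modulus barely matters to the *crystal-driven*
stress (the sweep of 0.5–11× E mostly re-samples the corner concentration
instead). The acceptance suite states the reference values at their own
tolerances and leaves the unreachable ones failing, with this section as the
analysis.

The expansion sweep ties the two regimes together: PCS(d) is the maximum of
affine functions of *d*, hence convex piecewise-linear. It starts at the
shoulder concentration (slightly decreasing), and the arg-max jumps to the
crystal-band edge near d ≈ 60–100 µm, after which the slope is the
crystal-collocated gain (~2.1 kPa/µm). Within any arg-max-constant range the
fit residual is at solver tolerance and the slope is exactly invariant to
luminal pressure (superposition; both are asserted to 1e-6 in the tests).

## Micro-OCT morphometry and the synthetic generator

A crystal in a cross-sectional B-scan is a pair of bright specular ridges.
`detect_crystal()` smooths the region of interest axially at the PSF scale
and laterally over ~2 A-lines (a matched filter: ridges are laterally
extended, speckle decorrelates beyond the PSF), thresholds at ROI median +
3·MAD, takes the two strongest axial maxima per column with parabolic
subpixel refinement, and drops columns whose ridge amplitude falls below
half the median candidate amplitude (this trims the blurred tails beyond
the crystal ends; columns whose surfaces merge below the axial resolution
never show two maxima and are dropped automatically). All criteria are
relative, so measurements are invariant to global intensity scaling.
`measure_crystal()` converts the lateral extent of valid columns to physical
length (lateral pixels are physical; 0.872 mm / 512 A-lines = 1.703 µm/px)
and the mean optical ridge separation to physical thickness by dividing by
the refractive index (1.33). The axial pixel count is not quoted with the
frame height, so the default is 1024 px over 1.4 mm (1.367 µm/px optical),
configurable.

The generator renders each crystal as two delta ridges separated by the
optical thickness in pixels, convolves with the Gaussian PSF (1.3 µm axial,
2.5 µm lateral FWHM), and blends unit-mean exponential multiplicative
intensity noise (fully developed speckle) with a contrast knob; 0.5 is the
default operating point and ground truth is emitted with every image, so
tests never infer truth from pixels. It emulates the geometry and
first-order statistics of a real B-scan, not confocal gating, depth
attenuation or refraction, so passing recovery tests demonstrate detector
correctness on plausible images rather than clinical performance. At the
default contrast, the median recovery error over 100 crystals is well under
1 axial px (thickness) and 2 lateral px (length). The cohort sampler draws
lengths from N(269.1, 80.16²) µm and thicknesses from N(3.0, 0.33²) µm,
rounds to whole pixels (which become the exact truth), and places crystals
away from the frame borders.

`sample_morphology()` draws the cap thickness uniformly over the observed
25–370 µm range and jitters lumen area, core arc and core area by ±10%
about their means, resampling any draw whose geometry does not close
(non-positive wall thickness); the stenosis closure is kept at its printed
value since jittering it mostly manufactures infeasible geometries. Every
sampled morphology must mesh with positive Jacobians, and does.

## Numerical choices and problem sizes

* 3×3 Gauss quadrature throughout (stiffness, loads, recovery); quadratic
  edge integration for pressure.
* Mesh validation checks Jacobian positivity at every quadrature point,
  edge conformity, and integrated region areas (core within 2%, total
  within 0.5%).
* Default problem sizes keep every scenario solve around two seconds:
  1188 elements (control) / 1296 (with crystal slot), ~7800 dof. The
  benchmark suite uses 8×24, 16×48, 24×72 annulus meshes; sweeps reuse one
  factorization per placement (the stiffness does not depend on *d*), and
  the stiffness-sensitivity sweep rescales only the crystal block of the
  assembled matrix.
* Ties in the PCS arg-max are broken by the first maximal node index;
  determinism is asserted byte-for-byte on the CSV outputs.

## Limitations

Linear kinematics with pressure on the undeformed configuration; no
contact, residual stress, pulsatility, or fluid–structure interaction; the
crystal is tangential (orientation effects are out of scope), loads the
abluminal cap face, and shares one thickness per mesh; the corner
singularity means absolute PCS values are reported at a stated mesh scale,
not as converged quantities.
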