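---
title: "Methods: plaque cross-section mechanics and model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plaque cross-section mechanics and model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and purpose

`plaquemech` quantifies how modelling simplifications change the mechanical
quantities used in coronary plaque vulnerability research: plaque wall
stress (PWS, the maximum principal Cauchy stress at the lumen), plaque wall
strain (PWSn, the maximum principal Green–Lagrange strain), and flow
(wall) shear stress (FSS). The compared model family is the one used in
multi-patient IVUS studies:

* **M1** — 2D cross-section with circumferential pre-shrink,
* **M2** — 2D cross-section without pre-shrink,
* **M5** — thin-layer (TL) model with circumferential *and* 10% axial
  shrink–stretch,
* **FSI** — the coupled surrogate: the TL structural model coupled
  sequentially to a cross-sectional flow solve,
* **M7** — flow-only on the imaged lumen.

Because patient VH-IVUS data are not public, the package ships a seeded
generator of synthetic segmented cross-sections so that every stage is
reproducible and testable end to end.

# Constitutive model

Wall and plaque components are hyperelastic, nearly incompressible, and
homogeneous per region. The strain-energy density is a modified
Mooney–Rivlin law,

$$W = c_1(\bar I_1 - 3) + c_2(\bar I_2 - 3)
    + D_1\!\left[e^{D_2(\bar I_1-3)} - 1\right]
    + \frac{K_1}{K_2}\left\{e^{K_2 (I_4-1)^2} - 1\right\}
    + \frac{\kappa}{2}(J-1)^2,$$

with $\bar I_1 = J^{-2/3} I_1$, $\bar I_2 = J^{-4/3} I_2$ the isochoric
invariants of $C = F^\mathsf{T}F$, $I_4 = n_c^\mathsf{T} C\, n_c$ the
squared stretch along the circumferential fiber direction $n_c$, and $J =
\det F$. The exponential fiber term is present only for the anisotropic
vessel/cap tissue and only in fiber tension ($I_4 > 1$), the standard
convention for exponential fiber models. Published coronary parameter sets
are built in as presets (`vessel`, `lipid`, `calcification`); see
`material_params()`.

Two normalization decisions matter and are deliberate:

1. **Fiber term normalization.** The anisotropic exponential is used in the
   Holzapfel-type form $(K_1/K_2)\{e^{K_2(I_4-1)^2}-1\}$, which vanishes at
   $I_4 = 1$. The variant with the $-1$ inside the exponent is nonzero in
   the reference state and would create reference stress.
2. **Isochoric invariants.** With the plain invariants $I_1, I_2$ the
   vessel preset (which has $c_1 = -1312.9$ kPa) carries a hydrostatic
   reference stress $2(c_1 + 2c_2 + D_1 D_2)I \approx 352\,\mathrm{kPa}\cdot I$:
   the imaged geometry would not be an equilibrium and the lumen would
   *contract* under internal pressure. The isochoric split — the standard
   treatment in nearly-incompressible mixed/penalty formulations, and what
   commercial FE codes use for this material class — makes the reference
   state exactly stress-free for every parameter set. `kinematics()` still
   reports the full invariants.

The volumetric penalty modulus defaults to $\kappa = \max(3000, 500\mu)$
kPa per material, where $\mu = 2(c_1 + c_2 + D_1 D_2)$ is the small-strain
shear modulus; for the vessel preset this is $\approx 61{,}200$ kPa
(effective Poisson ratio $\approx 0.499$). `material_params()` refuses
parameter sets whose small-strain response is unstable or that have a
negative-energy well near the reference state.

# Geometry, meshing and the structural solver

Segmented contours (lumen, outer wall, lipid-rich necrotic core,
calcification) are closed counterclockwise polygons in mm. The synthetic
generator builds them star-shaped about the lumen centroid; `build_mesh()`
exploits this with a component-fitted structured polar mesh: radial mesh
lines pass through every region interface, inclusion arc ends are snapped
to angular grid lines, and each quadratic (6-node) triangle carries exactly
one region label. Meshed region areas match the polygon areas to well
under 1% at the study resolutions.

The solver is a total-Lagrangian Newton iteration with a consistent
tangent. Lumen pressure is a follower load on the deformed boundary
(re-oriented every iteration, with its load stiffness included); the outer
wall is traction free; interface tractions are continuous because the
displacement field is conforming across region boundaries. Rigid-body
modes of the pure-traction problem are removed with three Lagrange
multipliers on the mean translation and rotation; since the pressure load
is self-equilibrated, the multiplier reactions vanish at convergence and
are reported as an equilibrium check (`reaction_norm`, typically
$<10^{-10}$ relative). Loads are applied incrementally (default 6 steps,
adaptively bisected on Newton failure) with a relative residual tolerance
of $10^{-8}$.

**2D vs thin layer.** The 2D variant is plane strain ($\lambda_z = 1$);
the kinematic assumption is not self-evident for vessel cross-sections,
but plane strain is the standard choice and is the limit consistent with
the thin-layer model. The thin-layer (TL) model is conceptually a 0.5 mm
extrusion of the slice whose axial faces are displacement-controlled to
impose the uniform stretch $\lambda_z = 1/0.9$ after the 10% axial shrink.
Because that boundary condition admits no axial variation, the extrusion
reduces *exactly* to the in-plane problem with $\lambda_z$ folded into the
3D invariants, which is how it is solved: the reduction is an identity,
not an approximation. The axial stretch is ramped in at zero pressure
before pressurization.

**Stress recovery.** Lumen-point PWS/PWSn are evaluated from nodal fields
recovered by per-element linear extrapolation of the Gauss-point values
(averaged over adjacent elements). Plain centroid averaging has an $O(h)$
inward bias at the boundary of order 10% on lumen stress at practical mesh
sizes — enough to distort the model comparison — whereas the extrapolated
recovery is within 0.4–1% of the ring benchmark oracle at study
resolutions.

`sample_lumen()` places 100 points on the lumen, counterclockwise from the
+x reference ray through the slice center. The default alignment for model
comparison is *material*: points uniform in undeformed arc length, mapped
through each variant's deformation, so point $i$ is the same material
particle in every variant. (A `deformed` alignment, uniform on the
deformed boundary, is also available.)

# Recovering the no-load geometry

The imaged geometry is the pressurized, axially stretched in vivo state.
`find_circ_shrink()` recovers a no-load surrogate: the lumen contour is
scaled by a ratio $k$ about its centroid, the outer contour is rescaled so
the no-load wall area equals the in vivo wall area times the axial stretch
(tissue volume conservation), and $k$ is root-found so that re-pressurizing
the shrunk geometry at the *imaging pressure* (plus the axial stretch for
TL models) recovers the in vivo lumen area. The search is a clamped secant
iteration starting at $k = 1$ (each function evaluation is a full FEM
solve; typically 3–5 evaluations), with the remap applied directly to the
mesh nodes so the topology is identical across iterates.

Choices and consequences:

* The imaging pressure is not generally recorded for IVUS pullbacks; the
  default is the diastolic pressure $P_\min$, configurable, and it is
  written into every report because it changes $k$.
* With diastolic imaging, 2D models give $k \approx 0.95$–$0.97$. For TL
  models the 10% axial stretch removes more lumen area than the imaging
  pressure restores, so the area-recovering ratio is slightly *above* one
  ($k \approx 1.02$–$1.04$): the bracket default is $[0.7, 1.1]$.
* The comparison study polishes the root to 0.1% lumen-area error
  (`study_config(shrink_tol = 0.001)`) even though the operation's
  contract is 0.5%: the M1-vs-M2 effect being measured is itself only a
  few percent of PWS, and a preconditioner allowed 0.5% slack can mask it.
* Opening angle / residual stress is out of scope, as is any per-component
  differential shrink.

# The flow surrogate

The full pulsatile 3D fluid–structure problem is replaced by steady, fully
developed laminar axial flow of a Newtonian fluid on the lumen
cross-section: $-\mu \nabla^2 w = G$ with $w = 0$ on the wall; FSS is
$\mu\,|\partial w/\partial n|$. This is the package's central scope
reduction and every FSS output is stamped `surrogate: fully-developed`.
The drive is a prescribed flow rate (default 1 mL/s, typical resting
coronary flow) shared across compared variants so that FSS differences
isolate geometry; viscosity defaults to 0.04 Poise. Wall shear is
recovered by the consistent boundary-flux method (nodal residuals of the
interior equation divided by tributary boundary length), which matches the
Poiseuille and elliptic-duct closed forms to a few tenths of a percent.

The **coupled (FSI-analog)** variant runs structure-then-flow
sequentially. Wall shear from axial flow acts axially and has no in-plane
resultant in a cross-section model, so the feedback is carried by the
slice's dynamic pressure instead: the structural lumen pressure is reduced
by $\tfrac12 \rho \bar v^2$ with $\bar v = Q/A$ and $\rho = 1$ g/cm³. This
keeps the structure-only vs coupled PWS difference small but nonzero
(~0.05%), the smallest structural disagreement, as expected for a one-way
coupling. The flow solve then runs on the deformed lumen and FSS is
interpolated at the same 100 material points as PWS.

# Comparison statistics

For aligned lumen points of models $p$ (base) and $q$:
$\Delta_i = |p_i - q_i|$, $\mathrm{Mean}\Delta = \sum_i \Delta_i / n$,
$\mathrm{Mean}_p = \sum_i p_i / n$, and the relative error is
$\mathrm{Mean}\Delta / \mathrm{Mean}_p \times 100\%$. Aggregation at
slice, patient and cohort level pools the points (one summation with $n$
the total point count), never a mean of means. For pairs involving the
flow-only model the compared samples are the per-slice FSS summaries
(Max-, Min-, Ave-FSS). Percentages are reported to two decimals and the
per-patient extreme errors are flagged, mirroring the published table
conventions.

# The synthetic cohort

`generate_cohort()` draws per-patient morphology and pressure ranges from
`cohort_variability()`. The defaults are fixed study conditions, chosen to
emulate a small clinical coronary cohort: lumen radius 1.3–1.7 mm, wall
thickness 0.9–1.2 mm, lumen eccentricity 0.15–0.45, lipid arcs 60–140°
with 0.10–0.25 mm fibrous caps, 30% calcification prevalence, diastolic
60–97 / systolic 110–145 mmHg, mid-vessel severity giving stenosis roughly
35–70% and plaque burden roughly 58–82%. Vessels carry 3 slices at 0.5 mm
spacing (matching the TL thickness; slice spacing is not otherwise
constrained). Noise is a band-limited radial perturbation (angular modes
2–5), never white noise, so contours stay simple.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: speckle and segmentation artifacts, non-star-
shaped lumens, vessel curvature and tapering, plaque component
heterogeneity beyond one lipid pool and one calcification band, and any
3D axial structure.

# Numerical choices and problem sizes

* Quadratic triangles, 6-point quadrature; element inversion guarded per
  integration point.
* Structural study mesh $h = 0.18$ mm with a flow mesh of 0.08 mm; the
  benchmark mesh-independence study (10% density steps, stop below 1%
  change in mean lumen PWS — `mesh_convergence()`) certifies the scale on
  the ring benchmark, and the per-slice M1-vs-M2 margins were checked to be
  refinement-stable at it. The 21-slice, 4-variant cohort study runs in a
  few minutes on one CPU (shrink searches and repeated solves warm-start
  Newton from the neighbouring converged state, which changes nothing at
  the $10^{-8}$ residual tolerance).
* The shrink target and the solver share one discrete area metric (the
  meshed lumen loop). Targeting the raw contour-polygon area instead would
  bias every preconditioned lumen outward by the inscribed-polygon
  representation gap (~0.5% at study resolution) — enough to distort the
  model comparison.
* Newton tolerance $10^{-8}$ relative; shrink root polished to 0.1% area;
  ties in the angular snap of inclusion arc ends resolved by dropping
  sliver grid lines below 20% of the nominal angular step.
* Degenerate inputs fail loudly: zero-area lumens, non-nested contours,
  infeasible cap/lipid/wall combinations, non-star-shaped contours and
  unstable material sets all raise explicit errors.

# Known limitations

* The flow surrogate cannot produce stenotic jets, recirculation or
  secondary flow: its flow-only vs coupled FSS differences are purely
  geometric (dilation and reshaping of the lumen under pressure). The
  disagreement still concentrates in Min-FSS — the compliant, lipid-backed
  sectors where FSS is lowest dilate the most — but the mechanism differs
  from full 3D FSI, where unsteady flow structures contribute.
* Cyclic bending and transient (multi-cardiac-cycle) dynamics are out of
  scope; quasi-static solves at the pressure extremes stand in for them.
* One scalar shrink ratio per slice; no opening angle; plane-strain 2D
  kinematics must be kept in mind when comparing against implementations
  that chose plane stress.

# Reproducing the study

```{r}
library(plaquemech)
cohort <- generate_cohort(7, base_seed = 42)
report <- cohort_report(cohort, study = study_config(load_steps = 4))
report            # cohort-level table
tidy(report, "patient")
autoplot(report)
```

`scripts/acceptance.R` re-runs the oracle benchmarks (constitutive
finite-difference check, ring inflation vs the 1D radial-equilibrium ODE,
Lamé small-load limit, Poiseuille/elliptic duct FSS, shrink fixed point,
mesh-independence protocol) and the full cohort comparison from scratch,
writing all quantities to JSON.
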