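---
title: "Designing and testing conforming spinal fusion cages on voxel grids"
author: "spinecage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and testing conforming spinal fusion cages on voxel grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Interbody cages used in lumbar fusion surgery can subside into the
vertebral endplates, particularly in patients with low bone mineral
density.  A cage that conforms to the patient's endplates *anatomically*
(shape) and *mechanically* (a porous internal architecture tuned to the
adjacent bone) spreads load more evenly and lowers the risk of endplate
overload.  `spinecage` implements, at desk scale, the full chain needed to
study this in silico:

1. a seeded generator of synthetic two-vertebra functional-spinal-unit
   (FSU) phantoms, standing in for patient CT data;
2. a structured-grid hexahedral finite element (FE) solver over the
   tri-domain model (implant design domain, bone, rigid embedding);
3. a robust three-field topology optimisation producing porous,
   mechanically conforming cage designs;
4. a factor-of-fracture-risk (FFR) subsidence assessment with a bilinear
   elasto-plastic bone model under a hyper-physiological follower load;
5. morphology metrics and iso-surface export of the optimised designs; and
6. the quantitative credibility activities (mesh convergence, sensitivity
   studies) plus the nonparametric cohort statistics.

Everything runs from a single seed, so every number the package reports is
reproducible bit for bit.

## Domains, units, and the voxel model

All computations share one geometric substrate, the `voxel_model`: an
isotropic structured grid (right-handed axes, z superior) with a per-voxel
label — `void`, `bone`, `implant_design`, `rigid` — and a per-voxel
apparent density in g/cm^3 for bone.  Mechanics are in mm-N-MPa; moments
are converted from Nm to Nmm on ingestion.  One trilinear 8-node hexahedron
per non-void voxel, tied (shared) nodes everywhere: the bone-implant
interface is conforming by construction, a deliberate simplification
relative to contact formulations (see *Deviations and limitations*).

The rigid embedding is realised as a very stiff elastic material (1000x the
largest bone or implant modulus present) rather than as kinematic
constraints; a stiffness-contrast test verifies that rigid-domain strains
stay below 1% of mean bone strains.  The bottom face is fixed in all
directions; loads are applied over the top-face nodes as the minimum-norm
nodal distribution that closes the requested force and moment resultants
about the xy-centre of the rigid domain (the exact nodal weighting is a
choice; any distribution with the same resultants differs only locally by
Saint-Venant's principle).

The linear systems are solved by sparse Cholesky factorisation in a
geometric nested-dissection ordering computed from the node coordinates
(the default fill-reducing ordering of the sparse backend performs poorly
on regular 3-D grids).  The symbolic factorisation is computed once per
problem and reused across design iterations and secant iterations.

## Bone material model

Apparent density maps to Young's modulus through the baseline power law
`E = 2383 rho^1.88` MPa, with the alternatives `E = 2100 rho - 80`
(the printed form of the Keller relationship is typographically ambiguous
between a linear law and a negative-exponent power law; the linear reading
is adopted and documented here) and `E = 4730 rho^1.56` (Morgan) used in
the density-law sensitivity study.  A floor of 25 MPa is applied after
whichever law is selected, which also removes the negative values the
linear law produces below 0.038 g/cm^3.  Poisson's ratio is 0.3.

In the assessment, bone follows a bilinear uniaxial law: elastic up to a
tensile yield strain of +0.73% and a compressive yield strain of -1.04%,
with a post-yield tangent of 5% of the elastic modulus.  Two variant modes
exist solely for the sensitivity study: `linear` and
`elastoplastic_symmetric` (both yields at the tensile magnitude).  Inside
the yield interval all modes coincide exactly — this identity, asserted to
machine precision in the tests, is the mechanism behind a 0.0% constitutive
sensitivity for a patient loaded in the linear regime.

Implants are titanium (E = 110 GPa, nu = 0.3, yield strain 0.7%, ultimate
10%) or PEEK (E = 3 GPa, nu = 0.43, yield 1.3%, ultimate 45%), elastic
up to yield and perfectly plastic beyond, with a failure flag at the
ultimate strain (published characterisations give yields and ultimates but
no hardening modulus for these implant materials, so none is assumed).

## The optimisation formulation

The design problem minimises the summed compliance of six daily-living
load cases (axial compression Fz = -177 N, posterior-anterior shear 27 N,
lateral shear 5 N, flexion 0.4 Nm, lateral bending 0.5 Nm, axial rotation
0.7 Nm, all scaled by body weight relative to the 51 kg reference patient)
subject to two constraints:

* **Bone strain**: the maximum principal strain in the bone domain under
  the axial compression case (the active case: endplate load transfer is
  shear-dominated, so the tensile limit governs and the minimum-principal
  constraint is omitted by default, with a research flag to enable it)
  must stay below 0.73%.  The per-element strains are aggregated with a
  p-mean of exponent 8 over normalised strains; the aggregation exponent
  is a free parameter of this implementation (a sharper exponent tracks
  the true maximum more closely at the cost of a harder optimisation
  problem).
* **Local volume**: neighbourhood solid-fraction averages of the dilated
  design over a radius of 3.5 element edge lengths, aggregated with a
  p-mean of exponent 16, must stay below 0.35.  This produces porous
  infill rather than a solid block.

Minimum feature size is controlled by the robust three-field scheme: raw
design variables are cone-filtered (radius 2.5 elements, a conventional
choice, deliberately smaller than the 3.5-element local-volume radius) and projected with a smoothed (tanh)
Heaviside at thresholds 0.7 / 0.5 / 0.3 into eroded / nominal / dilated
fields.  Objective and all FE solves for the compliance use the eroded
design (the worst-case stiffness convention); the strain constraint and the
local volume constraint are evaluated on the dilated design.  Evaluating
the strain constraint on the dilated field is the conservative reading (it
is the stiffest realisation pressing on the bone) and is the package's
choice, flagged here because robust formulations differ on this point.

Element stiffness interpolates as `E_min + x^3 (E - E_min)` with
`E_min = 1e-6 E` (penalty 3 and this void stiffness are the standard
choices).  Gradients use the self-adjoint compliance formula
and, for the strain constraint, the adjoint of the aggregated eigenvalue
functional with the eigen-derivative `n (x) n`, chained through projection
and filter; all gradients are verified against central finite differences
in the test suite on small grids.

The optimiser is a dense implementation of the Method of Moving Asymptotes
with the standard primal-dual interior-point subproblem solver and a move
limit of 0.2 (a constrained update is required by the two constraints,
ruling out optimality-criteria schemes; no MMA implementation exists in the
available R stack, so it is implemented in-package and exercised on an
analytic convex problem in the tests).

**Projection continuation at desk scale.**  The projection sharpness
follows the schedule beta in {2, 8, 32}, advancing every 20 iterations,
with at most 80 iterations; the loop stops once, at the final sharpness,
the design is feasible (constraint tolerance 1e-3), discrete
(M_nd < 3%, with `M_nd = mean(4 x (1 - x)) x 100`), and stagnant for three
consecutive iterations.  Longer, slower continuation schedules (final
sharpness 64 and hundreds of iterations) are common at cluster scale; the
desk-scale schedule reaches discreteness below 1% on the default problems
and is the package's own choice, stated here so that users scaling up know
which knob to turn (`topopt_config(beta_schedule=, beta_every=,
max_iters=)`).

A converged design reports, and the acceptance suite verifies, `g1 <= 1e-3`,
`v <= 1e-3` and `M_nd < 3%`.  On the default desk problems the strain
constraint is comfortably inactive (daily-living loads keep bone strains
far below 0.73%) and the design is shaped by compliance against the local
volume bound: material concentrates along the load paths and much of the
design domain stays empty, so the domain-referenced porosity of desk
designs (>= 90%) sits far above the porosity of cluster-scale patient
designs; only the bound `porosity >= 0.5` is asserted.

## Subsidence assessment

The assessment applies a compressive follower load of 310 N at the 51 kg
reference weight, scaled linearly with body weight, as a uniform traction
on the top of the model (transmitted through the rigid embedding to the
superior endplate; published follower-load definitions follow the spinal
curvature, and a uniform normal traction is the single-segment stand-in
here).  The load is applied in equal increments (10 by default); each
increment is solved quasi-statically by a strain-driven secant-stiffness
iteration: from the element's principal strains, the most-softening branch
of the bilinear law sets a secant factor `s = sigma(eps) / (E eps) <= 1`
per element, the stiffness is reassembled with `s E`, and the increment
iterates to a fixed point (tolerance 1e-3 on `s`, under-relaxation 0.6 —
the plain fixed point oscillates in deep post-yield states).  This is a
total-strain (deformation-theory) simplification of a rate-independent
elasto-plastic model: below yield every `s = 1`, so the assessment reduces
*exactly* to a single linear solve, and load increments change nothing.  An
increment that fails to converge is reported as collapse onset with the
last converged load fraction, never silently.

From the converged centroid principal strains, each bone element's factor
of fracture risk is `FFR = max(eps_max / 1.5%, eps_min / -2.0%)`; the
maximum over the bone domain is the subsidence-risk surrogate, and the
volume of elements with FFR > 1 quantifies the overloaded region.  Voxels
absorbed into the rigid embedding are excluded from the FFR field: strain
states inside the potting are artefacts of the embedding.

## The synthetic FSU phantom

The generator emulates the inputs the pipeline needs without any patient
data: two elliptical vertebral bodies (semi-axes 17 x 13.5 mm) partially
embedded in rigid potting slabs, concave (spherical-cap) endplates bounding
a 9 mm inter-body gap, a 1 mm cortical shell and endplates at twice the
trabecular density, and a correlated Gaussian random trabecular field
(FFT-smoothed white noise, correlation length 1.5 voxels, clipped at
0.01 g/cm^3) whose mean is set so that the *integral* vBMD of each
vertebra — the plain mean over the vertebra mask, shell included — matches
the requested target.  Cohorts spread vBMD targets over 0.15-0.54 g/cm^3
and draw body weights uniformly in 51-100 kg, the clinically representative
ranges for this application.  The default grid is 48^3 voxels over a
43.2 mm cube (0.9 mm spacing); the verification suite runs at 32^3
(1.35 mm) to keep a full optimisation in minutes on one CPU, and all
geometric parameters are physical, so grids refine consistently.

The endplate dishing depth is 2.7 mm — two voxels at the 32^3 working
resolution — so that a generic flat-faced cage (the largest flat slab that
fits the gap, resting on the peripheral endplate rim) and an
endplate-conforming spacer (the filled design domain) are geometrically
distinct at every supported grid.  These two reference implants drive the
directional checks: the conforming spacer must always produce a lower
maximum FFR than the flat cage on the same phantom, and across a cohort the
maximum FFR must correlate negatively with vBMD.

What the phantom does *not* emulate: real vertebral anatomy (posterior
elements, pedicles), CT acquisition physics (noise, beam hardening,
calibration error), trabecular microarchitecture (the continuum density
field carries no fabric anisotropy), and the intervertebral disc (assumed
resected).  Passing tests therefore demonstrate the correctness and the
qualitative behaviour of the algorithms, not clinical accuracy on real
patients.

## Credibility activities and statistics

`mesh_convergence_study()` re-runs the assessment over decreasing element
edge lengths and flags the first resolution whose successive percentage
difference in maximum FFR, `(current - previous)/previous x 100`, falls
below 5%; a homogeneous-modulus variant (350 MPa bone) decouples mesh
effects from the density field.  `sensitivity_study()` perturbs one axis at
a time — load magnitude by +/-2.5% and +/-25%, the density law (Keller,
Morgan vs baseline), or the constitutive model (linear, symmetric vs
asymmetric) — and reports the signed percentage difference per variant plus
the largest difference by magnitude.  In the elastic regime the load-axis
differences equal the applied variation exactly (FFR is linear in load) and
the constitutive axis is exactly 0.0%; both identities are asserted in the
tests, and a past-yield fixture verifies that the constitutive axis becomes
nonzero outside the linear regime.

Cohort comparisons use the median (seven patients allow no reliable
normality testing), pairwise median percentage reductions with two-sided
Mann-Whitney U tests (exact for tie-free samples up to n = 8 per group,
normal approximation otherwise), and Spearman rank correlations of maximum
FFR against vBMD; both statistics are delegated to base R (`wilcox.test`,
`cor.test`/`cor`) and cross-checked against brute-force enumeration oracles
in the tests.  No multiple-testing correction is applied, matching the
source conventions.  The qualitative ASME-V&V40-style tables ship as a
documentation template (`vv40_template()`) with no scoring logic: rigour
judgements are out of computational scope.

## Morphology and I/O

Optimised designs are binarised at 0.5 — the same threshold used for
iso-surface export.  Porosity is referenced to the design domain (the
source does not define its porosity denominator, so comparisons to printed
patient-specific values are caveated).  Pore diameters use the
local-thickness definition: per void voxel, the diameter of the largest
inscribed sphere containing it, computed from an exact Euclidean distance
transform with every maximal sphere painted (pruning by current coverage
would under-estimate near-wall thickness); the physical diameter of a
sphere with centre-distance radius `r` is taken as `2r + h` and capped by
the region's bounding extent.  Surfaces are extracted by iso-surfacing a
consistent six-tetrahedron (Kuhn) decomposition of each cell — unambiguous
and watertight by construction, verified by an Euler-characteristic and
edge-pairing check — and exported as binary STL.  Grids round-trip through
NIfTI (paired label/density volumes), fields through ASCII VTK image data
(`.vti`).

## Numerical choices at a glance

| Quantity | Value | Origin |
|---|---|---|
| SIMP penalty / E_min | 3 / 1e-6 E | convention (not stated in source) |
| Density filter radius | 2.5 elements | convention (not stated) |
| Local volume radius / fraction / p | 3.5 / 0.35 / 16 | source values |
| Strain limit / aggregation p | 0.73% / 8 | source / this package |
| Projection thresholds | 0.7, 0.5, 0.3 | robust-TO convention |
| Beta schedule | 2, 8, 32 every 20 it. | desk-scale choice |
| MMA move limit | 0.2 | convention |
| FE solve | sparse Cholesky, geometric ND ordering | this package |
| Secant tolerance / relaxation | 1e-3 / 0.6 | this package |
| FFR limits | +1.5% / -2.0% | source values |
| Modulus floor | 25 MPa, applied after every law | source / this package |
| Verification problem sizes | 32^3 optimisation, 16-24^3 assessments | desk-scale choice |

## Deviations and limitations

* The cluster-scale reference workflow assesses subsidence in an explicit
  dynamic solver with general contact on tetrahedral meshes; this package
  replaces that with an implicit quasi-static incremental solve with a tied
  voxel interface.  This is the single largest deliberate deviation: it
  removes micromotion and separation at the bone-implant interface from the
  model.
* Deformation-theory plasticity cannot represent unloading paths; it is
  exact below yield and a reasonable monotone-loading approximation beyond.
* At desk scale the optimised designs are sparse strut structures tuned to
  the daily-living loads; under the hyper-physiological follower load their
  thin struts concentrate compressive strain, so the package does not claim
  that desk-scale optimised designs lower the maximum FFR below the fully
  conforming spacer.  The verified directional effects are conforming vs
  flat interfaces and the negative maximum-FFR-vs-vBMD correlation.  (The
  compressive minimum-principal-strain constraint is available via
  `topopt_config(min_strain_constraint = TRUE)` for studying exactly this
  regime.)
* Cohort-scale headline effect sizes from patient CT studies (median
  maximum-FFR reductions, printed porosity values) are not reproducible at
  desk scale and are deliberately out of scope; the package reproduces the
  mechanistic identities and directional effects instead.
* The phantom's vBMD is exact by construction; how closely its density
  statistics match clinical CT is not addressed.
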