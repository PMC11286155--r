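---
title: "Modelling masticatory loading of the infant cranium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling masticatory loading of the infant cranium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioload)
```

## The problem

Between birth and roughly four years of age the human masticatory system
transforms: suckling gives way to biting and chewing, the jaw-closing
muscles (temporalis, masseter, medial pterygoid) grow severalfold in
cross-section, cranial bone stiffens by an order of magnitude, and the
cranial sutures and fontanelles close.  `cranioload` models how the forces
of this system load the growing cranium: it estimates muscle forces from
muscle cross-sectional areas, balances the temporal fascia against the
masseter's downward pull on the zygomatic arch, and solves the resulting
elastostatic problem on an age-parameterized skull model under three bite
modes, reporting bite forces, temporomandibular joint (TMJ) reactions, and
von Mises strain/stress fields.

Clinical CT geometry is not distributable, so the package generates every
input it needs: a parametric skull surrogate, synthetic muscle masks for
the sectioning protocol, and a synthetic measurement cohort.  The
quantities the pipeline is designed to reproduce are *ratios and patterns*
— force ratios between bite modes, the fascia-to-masseter force ratio, the
facial-versus-calvarial strain gradient — which depend on topology, lever
geometry and material contrast rather than on anatomical shape detail.
Absolute bite forces and strain magnitudes do depend on the true
geometries and are deliberately out of scope.

## The skull surrogate

`skull_params()` + `build_skull_mesh()` produce a stylized cranium as a
union of signed-distance primitives sampled on a regular voxel grid:

* an ellipsoidal calvarial shell (braincase) whose lower cap is the skull
  base;
* a facial plate with a palate slab and two pterygoid pillars that tie the
  palate back to the skull base;
* two slender tubular zygomatic arches, each anchored anteriorly in the
  lateral edge of the facial plate and posteriorly in a root block fused to
  the braincase wall, standing clear of the wall along their span.

Interior voxels are split into five tetrahedra with a checkerboard parity:
the two split variants are mirror images, and the grid is laid out so that
the mid-sagittal plane `x = 0` is a lattice plane.  The mesh is therefore
*exactly* bilaterally symmetric — mirrored nodes exist to the last bit —
which turns left/right symmetry checks into sharp tests rather than
tolerance judgements.

Element labels (bone plates, suture bands) are assigned from element
centroids; suture bands are geodesic strips around the metopic, coronal,
sagittal and lambdoid planes, an anterior fontanelle patch at the bregma, a
facial suture band where the plate meets the shell, and a synchondrosis
ring in the base.  A band is always at least one voxel layer wide per side
even when its nominal width (2 mm at 3 months, growing slightly with age)
falls below the pitch.  Suture patency follows a step schedule: all joints
at 3 months, calvarial sutures and fontanelle at 6, the fontanelle alone at
12, fully ossified from 24 months — the active set is monotone in age, and
closed sutures are relabelled as their host bone.

Growth: every linear dimension interpolates between 78 % of its 48-month
reference at 3 months and the reference at 48 months; facial *heights*
additionally take the growth factor to the power 1.35, so the face grows
relatively taller with age, shifting the bite points and lever arms the
way the real face does.  The shell thickness (4 mm) is held constant —
infant vault thickness changes far less than head size at this level of
stylization — and doubles as the resolution contract: the voxel pitch must
not exceed half the shell thickness, or `build_skull_mesh()` raises a
resolution error.

Default problem sizes: at the default 2 mm pitch the 48-month surrogate
meshes to ~68 000 tetrahedra (~23 000 nodes); the test suite also uses a
chunkier variant (3 mm pitch, 0.7 scale, 7 mm shell) of ~11 000 tetrahedra
for the property tests.

## Muscle forces

The maximum anatomical cross-sectional area (`csa_max()`) follows the
two-plane protocol: the mean of the areas cut by a reference plane P1 and a
second plane exactly 2 mm above it, measured by a Cavalieri voxel count.
Peak force is CSA times the muscle stress factor of 37 N cm^-2
(`peak_force()`); no pennation or physiological-CSA correction is applied.

The synthetic cohort (`generate_csa_cohort()`) draws 51 individuals spread
over 0–48 months.  Each muscle's expected CSA follows a monotone cubic
spline through anchors at 3 and 48 months; the anchors are the published
mean per-side forces divided by the stress factor.  The temporalis template
grows fast in the first 18 months, slows, then accelerates again; masseter
and medial pterygoid are near-linear.  Observed CSAs carry multiplicative
mean-one lognormal noise (default CV 10 %).  All draws are seeded.

`fit_growth()` regresses per-side force on age with a monotone I-spline
(integrated cubic B-spline) least-squares fit with nonnegative derivative
weights — the same basis that generates the cohort, so the zero-noise
cohort is recovered exactly.  Two estimator-design choices stabilize the
48-month end of the curve, where data are sparsest relative to the
boundary:

* the last four derivative weights are tied, which makes the growth rate
  constant (the curve linear) over the final spline segment — a
  natural-boundary condition; the generating templates live in the same
  constrained span;
* a second-difference curvature penalty on the derivative weights, with
  the penalty weight chosen by generalized cross-validation.  GCV selects a
  zero penalty on noise-free data, so exact recovery is preserved.

Even so, the 48-month value of a curve estimated from ~one individual per
month with 10 % multiplicative noise has an irreducible standard error of
roughly 3–4.5 % (it is a boundary-estimation problem); simulation across
seeds shows the three muscles' endpoint estimates land within 5 % of truth
simultaneously only about 60 % of the time.  Single-realization endpoint
checks at that tolerance are therefore expected to fail occasionally —
not from estimator bias (the Monte Carlo mean error is below 1 %) but from
the realized noise of the particular cohort.  95 % confidence bands come
from a residual bootstrap (500 resamples, seeded).

Muscle loads enter the model as force vectors (`build_vectors()`): three
per side per muscle, each running from an origin landmark towards its
insertion marker (the surrogate has no mandible, so insertion markers are
virtual direction targets), with magnitude equal to the per-side force
divided by the number of vectors, spread uniformly over the surface nodes
within 4 mm of the origin.  Left and right vector sets are exact mirror
images.  CSAs are measured on the left side only, mirroring the
measurement protocol's single-side convention.

## Materials and the elastic solver

Bone and cranial-joint tissue are isotropic linear elastic: at 3 months
421 MPa (bone, Poisson 0.22) and 30 MPa (joint, Poisson 0.30); bone
stiffens by 125 MPa per month to 48 months, joints by 100 MPa per month
with the modulus frozen after month 12.  Units are mm–N–MPa throughout;
strains are reported in microstrain.

The solver uses 4-node constant-strain tetrahedra assembled from the
closed-form isotropic element stiffness, a sparse Cholesky factorization
of the free-free block (constraint handling by row/column elimination),
and reaction recovery from the unmodified operator, `K u - f`, at the
constrained degrees of freedom.  The contract is the residual bound
(relative residual below 1e-8), not the method.  Nodal constraints fix all
three translations; solid elements carry no rotational degrees of freedom.
The von Mises equivalent strain uses the element material's Poisson ratio
as the effective ratio (the common commercial-solver elastic-strain
convention); it is configurable.

Constant-strain tetrahedra are stiff in bending, so absolute deflections
converge slowly (the cantilever benchmark in the test suite is ~6 % stiff
at the frozen refinement); the pipeline's reported quantities are force
ratios on a fixed mesh, which are far less sensitive to this than
absolute displacements.

## Temporal fascia balance

The temporal fascia inserts along the superior border of the zygomatic
arch and resists the masseter's downward pull.  Its force is unknown in
infants, so it is *solved for*: the minimum fascia force such that the
arch mid-span control node no longer deflects inferiorly.  Because the
model is linear, the control-node displacement is affine in the fascia
scale; one baseline solve and one unit-fascia solve give the balancing
scale in closed form (`solve_tff()`), verified by a re-solve and
cross-checked in the tests against a bisection search.  Both arches must
balance; the larger requirement is taken (they coincide on the symmetric
surrogate).  Only the inferior (arch) attachment is loaded — the
counter-force at the temporal lines is deliberately omitted, which is why
applying the fascia lowers the predicted bite force; an optional flag
applies the equal-and-opposite force for exploration.  An arch-length
scaling transfer (`scale_tff_by_arch_length()`) mirrors the
force-per-millimetre transfer procedure as an alternative to per-age
balancing; the two agree to ~20 % across ages, which is the fidelity of
that approximation here.

## Bite pipeline

Three modes: bilateral first molars (1), bilateral central incisors (2),
unilateral left first molar (3).  Bite nodes and two TMJ nodes per side
are fixed in all translations; the bite force is reported both as the sum
of reaction-vector magnitudes over the bite nodes and as the occlusal
(vertical) component, since the published scalar is not defined precisely.
Pre-eruption bite points sit on the alveolar margin, post-eruption on cusp
positions; in the surrogate both are generator-placed node sets.  Probe
values at the nine facial locations are volume-weighted averages of the
von Mises values of the elements sharing the probe node.  A rigid-body
oracle (`rigid_equilibrium_oracle()`) solves the static force/moment
balance with the bite idealized as a vertical support — for bilateral
modes the symmetric statics are uniquely solvable and reduce to lever
arithmetic; mode 3 uses a minimum-norm least-squares balance.

## Calibration of the default geometry

The real geometries being unavailable, the surrogate's default dimensions
and attachment layout were calibrated once against the finite-element
model and the rigid oracle, then frozen in the package defaults.  Three
constraints drove the calibration:

* the molar/incisor out-lever ratio places the incisor-to-molar bite-force
  ratio inside the published 73–88 % band;
* the fascia balance lands near 42 % of the per-side masseter force, with
  the temporalis ratio reported alongside;
* applying the balanced fascia reduces the molar bite force by 10–15 %.

The frozen layout distributes the masseter along the arch with a steep
(near-vertical) pull towards a ramus insertion marker and concentrates the
fascia near the arch mid-span, where its leverage on the deflection
criterion is greatest — mechanically, a near-midspan prop under a
distributed load.  An earlier candidate layout that met the three force
bands by loading the arch only near its ends was rejected because its
strain signature was wrong: balancing the fascia *increased* arch and
fronto-zygomatic strains, where the published pattern (and the prop
configuration) shows them decreasing.  The arch is deliberately slender
(2.2 mm reference radius) so that it behaves as a bending strut; the
coarse test-suite surrogate thickens it to the mesh-robustness floor, so
arch-bending phenomena are asserted only on the default-resolution
surrogate.

## What passing tests do and do not show

The surrogate reproduces the *mechanical organisation* of the infant
cranium — load paths, lever ratios, material contrast, suture schedule,
bilateral symmetry — under idealized geometry, and the synthetic cohort
reproduces the first two moments of plausible CSA growth, not the true
inter-individual distribution (the underlying per-individual measurements
are unpublished).  Agreement of the recomputed ratios with published
values therefore shows that the implemented pipeline embodies the same
mechanics, not that the surrogate predicts any real child's bite force.
Absolute forces in newtons, strain magnitudes, and shape-driven effects
(orbital, nasal, mandibular anatomy; inter-individual variation) are
outside what this artifact can support.

## Numerical choices and degenerate inputs

* Voxel parity alternation makes the 5-tet split conforming and
  mirror-exact; element orientation is repaired (not rejected) at build
  time, and genuinely inverted elements are an assembly error naming the
  element.
* Sectioning slabs are half-open intervals with a relative epsilon so a
  slab whose width equals the voxel spacing captures exactly one layer.
* The fascia solve raises a degeneracy error if the unit fascia load
  cannot move the control node, and returns zero force with a warning if
  the arch is not deflected inferiorly at baseline.
* Stage seeds are fanned out from the global seed by hashing the stage
  name; all generators are pure functions of (parameters, seed).
* Tolerances: solver residual 1e-8 relative; fascia balance residual
  1e-6 mm; zero-noise curve recovery 1e-6 relative.

## Limitations

Linear kinematics and materials (no suture contact or viscoelasticity);
no mandible, so joint reactions are cranial-side only; no organ loads
(brain, eyes); biting only, no chewing dynamics or occlusal-area effects;
desk-scale meshes (tens of thousands of elements, versus millions in a
production cranial model); and the fascia is a set of force vectors, not a
membrane.
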