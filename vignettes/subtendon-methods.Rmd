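---
title: "Modeling Achilles subtendon mechanics with subtendon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Achilles subtendon mechanics with subtendon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtendon)
```

## The scientific problem

The human Achilles tendon is not a uniform cable. It is built from three
semi-independent subtendons, one per head of the triceps surae (soleus,
medial and lateral gastrocnemius), which spiral about one another by roughly
90 degrees between the muscle and the calcaneus, and which can slide past one
another along a thin non-collagenous inter-subtendon matrix. Within each
subtendon the collagen fascicles are themselves twisted helically. Both
features have mechanical consequences: fascicle twist redistributes stress
across the tendon cross-section and changes the load at which the tissue
reaches a failure stress, and subtendon sliding determines how differential
soleus/gastrocnemius muscle forces translate into relative motion and strain
at the inter-subtendon interface -- quantities thought to matter for
tendinopathy and its rehabilitation.

`subtendon` implements this modeling chain end to end on synthetic,
parametric anatomy: geometry generation, twisted subtendon partitioning,
helical fiber fields, a transversely isotropic hyperelastic material, a
quasi-static finite element solver with tied/frictionless interface
conditions, the rupture and sliding experiments, and a dual-echo ultrashort
echo time (UTE) phantom module illustrating how such tendons are imaged in
the first place.

## Idealized geometry

Real subject-specific meshes come from segmented images morphed to
ultrasound morphometry. Here [generate_mesh()] builds an idealized stand-in:
an elliptical cross-section (areas and diameters configurable; defaults
60 mm free tendon + 20 mm calcaneal insertion, 70 mm^2 area, 6 x 15 mm
ellipse) extruded along the axis, meshed with trilinear hexahedra via a
smooth square-to-ellipse mapping. The requested `mean_csa` is honored
exactly by rescaling the ellipse semi-axes at the configured aspect ratio
(an exact 6 x 15 mm ellipse would have area 70.7 mm^2, not 70).

Two deliberately simple anatomical features carry the science:

* **A mediolateral centerline bow** (default 4 mm at mid-length, shape
  `4*z/L*(1 - z/L)`). A perfectly straight idealized tendon is
  mirror-symmetric, so fascicle twist could not redistribute anything; the
  bow supplies the asymmetry that subject-specific geometry provides in
  reality. With the bow set to zero the model is symmetric and the package's
  tests require the stress-asymmetry ratio to return exactly 1 within 2%.
* **A twisting angular partition** into subtendons. Sector widths follow the
  partition fractions (defaults SOL 0.52, MG 0.28, LG 0.20 -- the soleus
  subtendon is the largest; exact fractions are not published and are
  exposed in the configuration), anchored anatomically at the proximal end
  (soleus anterior, MG postero-medial, LG postero-lateral) and rotated
  internally by 90 degrees across the free tendon
  ([partition_twist_angle()] is linear in the normalized axial coordinate
  and constant through the insertion, where subtendons fuse with bone).

The two-subtendon sliding model merges MG and LG into a single
gastrocnemius subtendon and [split_interface()] duplicates the shared nodes
so the two bodies are joined only through coincident node pairs. Pair
normals are evaluated on the analytic twisted partition surface rather than
on the stair-stepped element facets: the faceted interface of a structured
hex mesh contains spurious axial-normal facets wherever the rotating sector
boundary crosses an element column, and penalizing those normals would
artificially block the axial sliding the experiment is about.

Population variability is emulated by [sample_population()]: independent
truncated normal draws (3 SD, positive) around the mean geometry.

## Fiber architecture

[build_fiber_field()] realizes a global fascicle twist angle `alpha` as a
helical unit direction field about the (bowed) centerline with uniform
axial twist rate `k = alpha / L_free`: at in-plane radius `r` and angle
`phi` the direction is the normalized helix tangent
`(-r k sin phi, r k cos phi, 1)` plus the centerline slope. The accumulated
rotation of peripheral fibers across the free tendon is then exactly
`alpha`, which the tests verify by integrating the discrete field along
element columns. At the axis the direction is axial; mirror-flipping the
side negates the circumferential component. [rotation_to_euler()] provides
the equivalent three-angle (intrinsic z-x-z) description of each direction,
with a round-trip accuracy requirement of 1e-8.

One consequence worth stating plainly: with this (standard) uniform-rate
mapping, a 60-degree total rotation over a 60 mm free tendon inclines even
the outermost fibers by only ~7 degrees from the axis. Twist therefore
modulates peripheral fiber load sharing but cannot weaken the tendon much
axially; see "Known limitations".

## Constitutive model

The tendon is a fiber-reinforced composite: collagen fascicles in a ground
substance. The strain energy density is

$$W(F) = \frac{c_1}{2}\left(J^{-2/3} I_1 - 3\right) + W_f(\lambda)
  + \frac{\kappa}{2}(J - 1)^2,$$

with $I_1 = F\!:\!F$, $J = \det F$ and fiber stretch
$\lambda = |F a_0|$. The fiber force $f(\lambda) = W_f'(\lambda)$ is zero in
compression, exponential in the uncrimping toe region and linear once the
fibers are straight:

$$f(\lambda) = c_3\left(e^{c_4 (\lambda - 1)} - 1\right) \;\;
  (1 \le \lambda < \lambda^*), \qquad
  f(\lambda) = c_5 \lambda + c_6 \;\; (\lambda \ge \lambda^*),$$

where $c_3$ and $c_6$ are derived by requiring value and slope continuity
at $\lambda^*$ ([continuity_constants()]).

Parameter defaults and their provenance:

| parameter | default | meaning |
|---|---|---|
| `c1` | 40 MPa | ground substance stiffness, taken as the neo-Hookean shear modulus (which coefficient the source estimate refers to is not stated; this mapping is an assumption) |
| `c4` | 13 | fiber uncrimping rate, dimensionless exponent |
| `c5` | 1390 MPa | modulus of the straightened fiber |
| `lambda_star` | 1.06 | toe-to-linear transition stretch; unreported alongside the other three, chosen as a typical tendon toe length, configurable |
| `kappa` | `100 * c1` | volumetric penalty (near-incompressibility) |

The analytic Cauchy stress ([cauchy_stress()]) is validated against central
finite differences of the scalar energy at a relative tolerance of 1e-5
over randomized deformation states, and the model's parameters are
recoverable to better than 0.1% from noiseless synthetic uniaxial data.

## Finite element solver

[solve_fe()] is a compact total-Lagrangian quasi-static solver over
8-node hexahedra: full 2x2x2 Gauss quadrature for the deviatoric and fiber
terms, and selective reduced integration for the volumetric penalty, with
5% of the penalty evaluated at the full quadrature points. That 5% fraction
is a stabilization: a purely central-point volumetric term leaves
local-dilatation (hourglass) modes without volumetric stiffness, and we
observed the assembled tangent acquire negative eigenvalues under tension
once those modes interact with the penalty's geometric stiffness. For the
same reason the default penalty is `kappa = 100 * c1` rather than a harder
value: at `1000 * c1` the pressure term's geometric stiffness drives a soft
lateral-sway mode of the long thin tendon unstable at ~3% stretch (a limit
point that persists under arbitrary increment refinement), while at
`100 * c1` the volume change stays below 1% at peak physiological loads.

Element residuals are exact; element tangents are central finite
differences of the residual (step 1e-6 mm) computed in compiled code, which
testing shows agree with directional derivatives of the global force to
~1e-10 relative error -- Newton converges superlinearly. Load is applied in
increments (adaptively halved on failure, up to 4 times). The step-length
rule accepts full Newton steps unless an element inverts; a strict
residual-decrease line search is deliberately not used because the residual
norm is a poor merit function for stiff penalty problems and was observed
to stall healthy non-monotone Newton sequences.

Boundary conditions: face sets can be fixed per component, prescribed an
axial displacement (uniaxial stretch runs), or loaded by dead tractions
distributed consistently over the reference face area. Two interface
conditions connect split subtendons: `tied` folds each slave degree of
freedom onto its master (exact coupling), `frictionless` penalizes only the
relative normal displacement of each pair (default 200 N/mm^3 times the
pair's tributary area) and leaves tangential slip free.

Two boundary-condition choices deserve their rationale:

* **Rupture grips.** Uniaxial stretch runs clamp the displaced proximal
  face in-plane as well as fixing the distal face. With a laterally free
  proximal face, a twisted fiber field generates an axial torque and the
  face spins into a torsional instability; physical grips do not allow
  this.
* **Guided proximal faces in the sliding model.** The muscle forces act
  axially on the proximal faces of the two subtendons, which are held
  in-plane. Without this the freed subtendon ends deflect laterally by
  more than 10 mm under the eccentric dead loads -- in vivo the free tendon
  is continuous with the aponeurosis and cannot do that.

## Rupture experiment

[simulate_rupture()] ramps the prescribed axial stretch (default steps of
0.4% up to 12%) and declares rupture when the maximum element von Mises
stress reaches a critical value, linearly interpolating the axial reaction
between the bracketing increments. The failure stress is a configurable
parameter (default 80 MPa): the underlying experimental failure load it
stands for is not printed in the source material, so the default is an
assumption on the order of reported tendon strengths. The stress-asymmetry
diagnostic ([stress_asymmetry()]) compares peak von Mises stress over the
medial and lateral halves of the mesh; redistribution comparisons across
twist angles are made at a common applied stretch so that differing failure
points do not confound the distribution pattern.

[sensitivity_analysis()] perturbs cross-sectional area (relative SD 0.15),
tissue stiffness (`c1` and `c5` jointly, relative SD 0.15) and twist angle
(SD 10 degrees about a 30-degree mean) one at a time by one standard
deviation and reports the relative rupture-load change per SD; the SDs are
literature-style magnitudes chosen once, not fitted. [anova_one_way()]
provides the classical F test used to compare rupture loads between
twist-angle groups (cross-checked in the tests against
`stats::oneway.test`).

## Sliding experiment

[run_activity()] loads the two-subtendon model with one of five packaged
activity force pairs (peak soleus force and simultaneous gastrocnemius
force: two-legged heel drop 680.6/457.6 N, one-legged heel drop
1464.0/836.4 N, one-legged heel drop with knee bent 2371.2/475.1 N, toe
walking 1242.6/457.6 N, hopping 3777.4/1816.8 N), solves under frictionless
or tied contact and reports:

* `sliding_mm` -- maximum relative *longitudinal* (axial) displacement of
  paired interface points. Subtendon sliding is longitudinal by
  definition; the full tangential slip magnitude is reported alongside
  (`tangential_slip_mm`) but is dominated by circumferential untwisting
  that simply scales with total force.
* `differential_lengthening_mm` -- difference of the subtendons'
  lengthenings, measured as proximal-face mean axial displacements (means
  are robust to the axial-displacement gradients whole-body bending
  superimposes on per-node maxima).
* `max_interface_strain` -- maximum first-principal Green-Lagrange strain
  over the elements adjacent to the interface, both sides.

Under frictionless contact the knee-bent one-legged heel drop produces more
differential lengthening than hopping despite much smaller forces, because
its soleus/gastrocnemius force ratio (5:1) puts the lightly loaded
gastrocnemius in the compliant toe region while hopping loads both
subtendons into the stiff linear region; interface strain, in contrast,
tracks the soleus force in rank exactly. Tying the interface lowers both
sliding and interface strain for every activity. One caveat this model
states openly: with exact tied coupling on this thin idealized geometry the
shear-lag transfer length (~19 mm) is much shorter than the free tendon, so
tied contact removes nearly all differential motion (94-100% reduction),
a larger relative reduction than in interface strain (40-60%).

## Dual-echo UTE phantom

Collagen-rich tissue loses its MR signal within ~1 ms of excitation
(T2* ~ 1 ms), so conventional echo times show tendon as a void. The
[simulate_echo()] model is deliberately minimal: mono-exponential decay
$S = S_0 e^{-TE/T_2^*}$ per voxel on a labeled phantom (defaults: tendon
T2* 1 ms, muscle 30 ms, fat 40 ms, cortical bone 0.4 ms), optional Gaussian
noise under a fixed seed, no k-space simulation, no T1/TR/flip saturation
(the sequence's TR and flip angle are recorded but unused -- the subtraction
rationale lives entirely in TE and T2*). Subtracting a short-TE image
(default TE2 = 2.54 ms) from an ultrashort-TE image (TE1 = 0.08 ms) cancels
the slowly decaying tissues and leaves the tendon bright;
[te2_sweep()] shows the tendon-muscle contrast of the subtracted image
rising to an optimum and then falling as longer second echoes let muscle
signal into the difference.

## Problem sizes and numerical defaults

The package's experiments and tests run at deliberately modest sizes,
chosen as a balance between discretization quality and turnaround on a
single CPU: the headline rupture sweep uses a 6x6 section by 14 layers
(~500 hexahedra; the twist-angle ordering was additionally checked at
~1150 elements), sliding comparisons use 4x4 x 10 layers, and unit tests
use smaller boxes and 4x4 x 8 tendons. Solver defaults: relative residual
tolerance 1e-6, at most 50 Newton iterations per increment, 10-30 load
increments per run, contact penalty 200 N/mm^3, FD tangent step 1e-6 mm.

## What the synthetic data does and does not show

The generator emulates the *features that carry the mechanisms* -- aspect
ratio, mediolateral bow, twisted partition, population spread of
morphometry -- not real anatomy: cross-sections are perfect ellipses, the
insertion is a straight extrusion rather than a flaring enthesis, the LG
subtendon's early calcaneal insertion is not modeled, and material
parameters are homogeneous. Passing tests therefore demonstrate that the
implemented mechanisms behave as described on idealized anatomy; they do
not validate subject-specific stress magnitudes.

## Known limitations

* With the uniform-twist-rate fiber mapping on this geometry, increasing
  fascicle twist monotonically *strengthens* the model tendon (by ~5% from
  0 to 60 degrees): twist redistributes the bow-induced peripheral stress
  concentration, and the <= 7-degree fiber inclinations are too small to
  weaken the tendon axially at high twist. An interior optimum at 15-30
  degrees, as reported for subject-specific anatomy, does not emerge from
  the idealized bowed ellipse; the package reports all pairwise percent
  differences so this remains visible rather than hidden.
* Tied-vs-frictionless comparisons inherit the shear-lag caveat above.
* The solver is quasi-static and the material elastic: no viscoelasticity,
  damage, fatigue, or dynamic effects; "rupture" is a stress criterion, not
  crack propagation.
* Frictionless contact is small-slip (penalty on reference-configuration
  pair normals); large-slip sliding with changing contact partners is out
  of scope.
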