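---
title: "The Virtual Eye: models, numerics and design choices"
author: "eyevit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Virtual Eye: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyevit)
```

`eyevit` simulates how an intravitreally injected anti-VEGF drug
(bevacizumab, ranibizumab, aflibercept) spreads through the human
vitreous body over the month between two injections, and scores a
therapy by how much drug reaches the macula versus how much is lost
through the retina. This vignette explains the model, the numerical
methods, every tunable parameter with its default and provenance, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the underlying physics or published descriptions
leave freedom.

## 1. Geometry: a personalized vitreous from ultrasound points

The meridian profile of the vitreous is a modified Limacon
$$x = R(q,\varphi)\cos\varphi + m_x,\qquad y = R(q,\varphi)\sin\varphi,
\qquad R(q,\hat\varphi) = q_1 + q_2\cos\hat\varphi + q_3\cos^3\hat\varphi ,$$
revolved about the optic ($x$-) axis. Four scalars personalize the
shape: `q1` sets both the axial depth and the equatorial width (both
are $2q_1$ for this family), `q2` and `q3` shift volume between the
posterior and anterior halves (the anterior flattening at the lens),
and `mx` recentres the polar representation.

`fit_limacon()` estimates $(q_1,q_2,q_3,m_x)$ from extracted
ultrasound profile points by damped Gauss-Newton least squares on the
radial residuals $r_i - R(q,\hat\varphi_i(m_x))$, with the analytic
Jacobian, including the dependence of $\hat\varphi$ on $m_x$. The
problem has four well-separated scalars and converges from the
centroid/mean-radius initial guess in a handful of iterations; steps
that would make the profile non-positive are rejected by increasing the
Levenberg damping. `arccos` alone recovers angles only in $[0,\pi]$;
the sign of $y$ restores the full circle.

The **default average eye** is `limacon_params(10, 1, 0.5, mx = 0.5)`:
a 20 mm globe with ~4.2 mL vitreous volume, sitting between the
anatomical axial depth (~17 mm) and equatorial width (~21 mm) that a
single Limacon cannot reproduce simultaneously.

The boundary is partitioned by polar angle from the posterior pole:
the **lens** is the anterior cap of half-opening 30 degrees, the
**hyaloid** inflow band the adjacent 10-degree annulus, and the
**retina** everything else; all three angles are configurable
(`boundary_spec()`). The macula is the ball of radius 2 mm around the
posterior pole intersected with the domain; the centre can be offset
along the meridian to distinguish macula from optic-nerve head.

### Synthetic ultrasound scans

`generate_synthetic_us_points()` places `n` points (a clinical B-scan
extraction yields 164) at equally spaced angles on a known profile and
perturbs the radius with centred Gaussian noise (default sd 0.1 mm,
the order of the pixel size of a B-scan). It emulates *radial
extraction noise only*: real scans also carry angle-dependent bias
(probe orientation), partial arcs, and correlated segmentation errors.
Passing tests on these fixtures therefore demonstrates the estimator's
correctness and precision under honest noise, not robustness to
systematic scan artefacts.

## 2. Aqueous-humor flow: a mixed Darcy solver

A small fraction of the aqueous humor produced at the ciliary body
percolates the vitreous and leaves through the retina. The package
solves the steady Darcy model
$$v = -\frac{\kappa}{\mu}\nabla p,\qquad \nabla\cdot v = 0,$$
with no-flux on the lens, a Poiseuille inflow profile
$c_{\rm pflow}(R_{\rm pflow}^2 - r_{\rm pflow}^2)$ on the hyaloid band
(where $r_{\rm pflow}$ is the 3d distance to the circle of revolution
through the midpoint of the band and $R_{\rm pflow}$ half the meridian
chord between the band edges), and the membrane relation
$n\cdot v = K_{\rm RCS}(p - P_v)/L$ on the retina.

Discretization uses lowest-order Raviart-Thomas facet fluxes for the
velocity and elementwise-constant pressures. The saddle-point system
is solved by the Schur-complement method: the velocity block (with the
retinal Robin augmentation, which also removes the pure-Neumann
pressure nullspace, so no gauge fixing is needed) is factorized by
sparse Cholesky and the pressure system is solved by conjugate
gradients to a relative residual of 1e-12. The solve works with the
gauge-shifted pressure $p - P_v$ so that the iteration's stopping test
scales with the flow, not with the venous pressure offset; a direct
sparse factorization of the (equilibrated) full saddle matrix is kept
as a cross-check and agrees to ~1e-9.

**Flow parameters** (`flow_params()`, none printed in clinical
sources with certainty; all overridable):

| parameter | default | unit | rationale |
|---|---|---|---|
| `kappa` | 6.9e-15 | m^2 | vitreous permeability; with `mu` gives conductivity 1e-11 m^2/(Pa s), i.e. a pressure drop of a few Pa across the vitreous |
| `mu` | 6.9e-4 | Pa s | aqueous humor at 37 C (close to water) |
| `Pv` | 1200 | Pa | episcleral venous pressure (9 mmHg) |
| `K_RCS`, `L` | 4.5e-15, 1e-3 | m^2/(Pa s), m | lumped retina-choroid-sclera conductance `K_RCS/L` = 4.5e-12 m/(Pa s); a few hundred Pa transretinal difference at default flow |
| `aqueous_production` | 2.5 uL/min | | textbook production rate |
| `vitreous_fraction` | 0.1 | | share of production routed through the vitreous |

The inflow strength `c_pflow` is never set by hand: it is calibrated
(`calibrate_inflow()`) so that the analytic surface integral of the
Poiseuille profile over the revolved band equals
`aqueous_production * vitreous_fraction`. Whether `K_RCS` already
contains the thickness cannot be resolved from published descriptions;
the package treats `K_RCS/L` as the lumped conductance and documents
both numbers.

## 3. Drug transport: convection-diffusion with a fractional-step theta scheme

The concentration obeys
$$\partial_t C + (v\cdot\nabla)C - \nabla\cdot(D\nabla C) = 0,$$
with zero flux at the lens, $C = 0$ on the hyaloid (the drug does not
diffuse against the inflow; a future anterior-chamber coupling would
relax this), and at the retina the membrane condition
$$P\,C + (n\cdot v)\,k\,C = -D\,\partial_n C + (n\cdot v)\,C .$$
The published typesetting of this condition is ambiguous about the
grouping of the advective terms; the package implements the net
outflux reading, $-D\partial_nC + (n\cdot v)C = (P + (n\cdot v)k)\,C$,
i.e. a Robin coefficient $P + (n\cdot v)(k-1)$ in the weak form. With
the neutral default $k = 1$ the two readings coincide.

**Transport parameters** (`transport_params()`):

* `D = 4e-11` m^2/s: bevacizumab in vitreous (rabbit measurement);
  2e-11 and 8e-11 are used as lighter/heavier comparators.
* `P = 6e-9` m/s: retinal permeability. Not measurable directly; the
  default sits centrally in the published 1e-9..1e-8 m/s span for
  transretinal antibody loss. Note that in this model the hyaloid sink
  and the through-flow contribute substantially to clearance, so the
  realized 30-day retention is below what a single-compartment
  half-life fit would suggest for the same `P`.
* `k = 1`: neutral vitreous/retina partitioning.
* `v_settle`, `gravity_dir`: gravity enters as an additional constant
  transport velocity $v_{\rm settle}\,\hat g$. The Stokes estimate
  `stokes_settling_speed(5e-9)` for a 148 kDa antibody monomer is
  ~3e-11 m/s - negligible against both diffusion and flow, which is
  why head orientation barely matters in the default model. Larger
  values (aggregates, heavy formulations) can be set explicitly.
* Anisotropic diffusion along collagen fibrils is supported as a
  constant SPD tensor `D` (full-3d mode only); no spatially varying
  fibre field is modelled.

Space is discretized with continuous piecewise-(bi/tri)linear elements
on the same mesh as the flow; the convection term uses the elementwise
linear Raviart-Thomas velocity reconstruction. No convection
stabilization is applied: at the default resolution the cell Peclet
number is ~0.05, far below the oscillatory regime.

**Mass treatment.** The concentration mass matrix is row-sum
**lumped** by default. With the consistent Galerkin mass matrix, the
sharp injected bolus excites mesh-scale ringing with undershoots of
about -1% of the peak; lumping reduces this to below -0.01% while
keeping second-order spatial accuracy. `mass = "consistent"` restores
the pure Galerkin operator (used by the temporal verification study,
where linear-in-space fields are then exactly represented).

**Time integration** is the strongly A-stable fractional-step theta
scheme: sub-steps $\theta\Delta t,(1-2\theta)\Delta t,\theta\Delta t$
with $\theta = 1-\sqrt2/2$ and implicitness
$\alpha = (1-2\theta)/(1-\theta)$ on the outer sub-steps (its
complement on the middle one). This classical pairing makes all three
sub-step matrices equal to $M + \alpha\theta\Delta t\,A$, so one
factorization per operator serves the entire horizon. The macro step
defaults to 0.25 days (halved during the first day to resolve the
bolus transient). Sub-systems are solved by a cached sparse LU
factorization - at this problem size (1e4-2e4 unknowns) a direct solve
is faster and more robust than restarting an iterative method
hundreds of times, and trivially meets any algebraic-residual
tolerance; the Krylov alternative matters only at resolutions far
beyond the package's intended desk scale.

**Initial bolus**: a spherical indicator of radius 2.29 mm (0.05 mL)
at the needle tip with a half-cell linear rim, rescaled so the
discrete mass equals the dose exactly (1.25 mg default). Boluses
clipped by the boundary keep the full dose. All therapy functionals
are dose-invariant by construction; absolute concentrations are not.

**Head-orientation schedules** re-assemble the convection operator at
each switch; factorizations are cached per orientation, so an
alternating schedule pays the assembly cost once per orientation, not
per switch.

## 4. Therapy functionals

With $M = B_r(m)\cap\Omega$, $r = 2$ mm:

* $J_\Omega(t) = \int_\Omega C(t)\,dx / \int_\Omega C(0)\,dx$ - the
  fraction still in the vitreous;
* $J_M(t) = \int_M C(t)\,dx$ - the drug amount at the macula (kg);
* $J_{M,\Omega}(T) = \int_0^T J_M(t)\,dt / \int_\Omega C(0)\,dx$ -
  time-integrated macular exposure, by trapezoid on the output grid
  **with time in days** (the natural clinical unit; the published
  description leaves the time unit of this integral unstated). It
  deliberately overestimates the drug able to act, since residence is
  counted repeatedly;
* $J_R(T) = 1 - J_\Omega(T) - J_{M,\Omega}(T)$, the conservation form
  of the retinal-loss functional. (The published typesetting has a
  `+` before $J_{M,\Omega}$, but the printed drug-fate partitions -
  50/40/10 and 80/20/0 summing to one - require the minus; the
  conservation form is implemented.)

$\int_M$ uses quadrature-point membership with one level of midpoint
subdivision in cells cut by the sphere; a point exactly on the sphere
counts as inside. This bounds the geometric bias mesh-independently
(verified against the sphere-sphere lens-volume closed form to ~1%).

## 5. Verification

`convergence_study()` runs two manufactured-solution studies:

* **space**: a trigonometric steady field with matching source and
  Dirichlet data; the axisymmetric variant manufactures the
  *cylindrical* Laplacian. The steady convection-diffusion solve
  isolates spatial error. Observed L2 orders: ~2.0 (axisymmetric),
  ~2.1 (full-3d).
* **time**: a field linear in space (exact in P1 with the consistent
  mass matrix) decaying as $e^{-\lambda t}$; stepping isolates the
  temporal error of the theta scheme. Observed order ~2.0.

`flux_audit()` closes the drug budget: dose = remaining + cumulative
retinal outflux (boundary quadrature accumulated with the scheme's own
sub-step weights) + cumulative hyaloid outflux (Dirichlet-row residual
bookkeeping). The identity holds at machine precision when - and only
when - the divergence-free flow, the boundary quadratures and the
Dirichlet bookkeeping are mutually consistent, which is what makes it
a useful end-to-end check (it caught a real assembly bug during
development at a 29% imbalance).

## 6. Meshes and problem sizes

`full-3d` meshes subdivide the cube lattice into six Freudenthal
tetrahedra per cell and map it onto the revolved Limacon with the
smooth cube-to-ball map (the naive sup-norm radial map creates sliver
cells on the cube diagonals - volume ratios of 4e5 - which inflate
round-off in the flux audit; the smooth map keeps the ratio ~200).
`axisymmetric-2d` meshes triangulate the full meridian profile region
polar-wise; cylindrical integrals use the weight $\pi|y|$ so the
doubled half-plane counts once. Axisymmetric mode exists as a fast,
verifiable path for rotationally symmetric configurations and refuses
symmetry-breaking scenarios (off-axis bolus, $\psi_z \ne 90^\circ$,
lateral gravity); an on-axis scenario agrees between the two modes to
within 5% in $J_M$.

Production runs in this package use h ~ 1.1 mm (about 9000 velocity
cells and 1e4 concentration unknowns in 3d) and 120 macro steps per 30
days; the resolution study and the coarse-mesh agreement above justify
these as adequate for fraction- and timing-type conclusions (a 1.4 mm
mesh moves the functionals by a few percent relative).

## 7. Known limitations

* The vitreous is homogeneous and Newtonian-porous; no liquefaction,
  viscoelasticity or fluid-structure interaction.
* No drug-VEGF binding kinetics or degradation: the functionals are
  transport surrogates, and $J_{M,\Omega}$ in particular overestimates
  pharmacological action.
* The hyaloid condition $C=0$ is an absorbing idealization; it makes
  total clearance faster than clinical single-compartment half-life
  fits, and a coupled anterior-chamber model would soften it.
* Absolute drug-fate percentages depend strongly on the unpublished
  physiological parameters above; orderings, ratios and timing
  (which angle is better, how much is lost relative to a baseline,
  when the macular amount peaks) are the robust outputs.
* The injection jet itself is not modelled; the bolus appears at rest
  at the needle tip.
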