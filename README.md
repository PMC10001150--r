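# eyevit — a Virtual Eye for intravitreal drug-distribution simulation

Age-related macular degeneration is treated by repeated intravitreal
injections of anti-VEGF antibodies (bevacizumab, ranibizumab,
aflibercept). Where the needle enters, at which angles it is tilted,
how the patient holds their head afterwards, and how heavy the drug
molecule is all change how much drug ever reaches the site of action —
the macula — before it is washed out through the retina. `eyevit` is a
finite-element simulator for exactly these questions, aimed at
modellers and ophthalmic-pharmacology researchers who want a
transparent, scriptable, fully open implementation.

## The model

**Geometry.** The vitreous body is a personalized solid of revolution:
a modified Limacon profile

  R(q, φ̂) = q₁ + q₂ cos φ̂ + q₃ cos³ φ̂,  x = R cos φ + mₓ, y = R sin φ,

whose four parameters are fitted to extracted ultrasound B-scan points
by damped Gauss–Newton least squares. The boundary splits into retina
Γ_R, lens Γ_L and the hyaloid inflow band Γ_H.

**Aqueous-humor flow.** A small fraction of aqueous production
percolates the vitreous, modelled as steady Darcy flow

  v = −(κ/μ) ∇p, ∇·v = 0,

with no flux through the lens, a Poiseuille inflow profile on the
hyaloid band, and the membrane relation n·v = K_RCS (p − P_v)/L on the
retina. Discretization: lowest-order Raviart–Thomas fluxes +
elementwise-constant pressures; solved by a Schur-complement method
(sparse Cholesky inside, conjugate gradients on the pressure).

**Drug transport.** The concentration obeys the convection–diffusion
equation ∂ₜC + (v·∇)C − ∇·(D∇C) = 0 with C = 0 on the hyaloid, zero
flux on the lens, and the retinal membrane condition
P C + (n·v) k C = −D ∂ₙC + (n·v) C. Gravity enters as an additional
settling velocity; anisotropic diffusion as a constant SPD tensor.
Time integration uses the strongly A-stable fractional-step θ scheme
(θ = 1 − √2/2, second order); space uses continuous piecewise-linear
elements on the same mesh. Verified quadratic convergence in both
space and time on manufactured solutions.

**Therapy functionals.** J_Ω(t) — fraction of the dose still in the
vitreous; J_M(t) — drug amount in the 2 mm macular ball; J_{M,Ω}(T) —
time-integrated macular exposure (days); J_R(T) = 1 − J_Ω − J_{M,Ω} —
the share lost through the retina. All are dose-invariant.

## A worked example

```r
library(eyevit)

# 1. personalize the geometry from (here: synthetic) ultrasound points
pts <- read_us_points(system.file("extdata", "synthetic_us_points.csv",
                                  package = "eyevit"))
fit <- fit_limacon(pts)
print(fit)
#> Limacon fit (converged, 11 iterations)
#>   max |residual| = 0.2942 mm, rms = 0.09761 mm
#> Modified-Limacon vitreous profile
#>   q = (10.02, 0.5952, 0.5323) mm, mx = 0.8715 mm
#>   axial depth 2*q1 = 20.03 mm, R(0) = 11.14 mm, R(pi) = 8.89 mm

# 2. run the standard pars plana injection for 30 days
cfg <- scenario_config(h_mm = 1.4, label = "standard-injection")
res <- run_scenario(cfg)
print(res)
#> Scenario 'standard-injection'
#> Transport run: 125 output times over 30 days
#>   J_omega(T) = 0.0048   J_M_omega(T) = 0.0152   J_R(T) = 0.9799
#>   peak J_M = 1.737e-09 kg at 6.75 days
#>   flux audit imbalance: 1.95e-12% of the dose
```

Reading: of a 1.25 mg bevacizumab bolus injected 3.5 mm behind the
limbus at ψ_xy = 50°, the macular drug amount peaks 6.75 days after
the injection; after 30 days only 0.5% of the dose is still in the
vitreous, the integrated macular exposure is 1.5% · days of the dose,
and the rest has left through the retina (92%) and the hyaloid (7%) —
the discrete drug budget closes to 12 significant digits
(`flux_audit(res$run)`).

Comparative questions go through `sweep_scenarios()` (needle angles,
injection positions, diffusion coefficients) and `head_schedule()` /
`alternating_schedule()` (posture). A thin command-line interface is
installed as `exec/eyevit` (`fit-geometry`, `mesh`, `flow`, `run`,
`sweep`, `verify`, `report`), reading single-file YAML scenario
configurations (see `inst/extdata/default_params.yaml` for all
physical defaults with provenance notes).

The methods vignette (`vignettes/virtual-eye-methods.Rmd`) documents
the model assumptions, every parameter default, the numerics
(meshing, solvers, mass lumping, the flux audit) and known
limitations.

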