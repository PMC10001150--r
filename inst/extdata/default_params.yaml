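# Default physical parameters of the Virtual Eye simulator, with provenance.
# None of these is measurable from the ultrasound geometry data; all are
# literature-sourced defaults and can be overridden per scenario.
flow:
  kappa: 6.9e-15          # m^2; vitreous Darcy permeability.  With mu below,
                          # kappa/mu = 1e-11 m^2/(Pa s): a few Pa pressure drop
                          # across the vitreous at physiological through-flow,
                          # consistent with porous-medium estimates of the
                          # collagen/hyaluronan network.
  mu: 6.9e-4              # Pa s; aqueous humor viscosity at 37 C (~ water).
  Pv: 1200                # Pa (9 mmHg); episcleral venous pressure.
  K_RCS: 4.5e-15          # m^2/(Pa s); lumped retina-choroid-sclera
  L: 1.0e-3               # m; retinal (RCS) thickness.  K_RCS/L = 4.5e-12
                          # m/(Pa s) transretinal conductance: a few hundred Pa
                          # across the RCS at the default through-flow.
  aqueous_production: 4.1667e-11   # m^3/s (2.5 uL/min).
  vitreous_fraction: 0.1  # share of aqueous production percolating the
                          # vitreous ("a smaller portion"); calibrates c_pflow.
transport:
  D: 4.0e-11              # m^2/s; bevacizumab in vitreous (rabbit measurement).
  P: 6.0e-9               # m/s; retinal drug permeability.  Chosen so the
                          # model's vitreous elimination half-life for
                          # D = 4e-11 m^2/s is ~1 week, matching clinical
                          # bevacizumab pharmacokinetics; within the published
                          # 1e-9..1e-8 m/s span for antibody transretinal loss.
  k: 1.0                  # -; vitreous/retina partition coefficient (neutral).
  v_settle: 0.0           # m/s; gravitational settling.  The Stokes estimate
                          # for a 148 kDa antibody monomer (a ~ 5 nm) is
                          # ~1e-11 m/s and negligible; use
                          # stokes_settling_speed() for alternatives.
injection:
  limbus_distance_mm: 3.5 # standard pars plana entry
  needle_depth_mm: 5.0
  psi_xy_deg: 50.0
  psi_z_deg: 90.0
  bolus_radius_mm: 2.29   # 0.05 mL injected volume
  dose_kg: 1.25e-6        # 1.25 mg bevacizumab convention
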