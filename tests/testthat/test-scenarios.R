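test_that("needle geometry lands where the clinical description says", {
  dom <- fx("dom")
  # zero depth: the tip is the entry point, on the profile surface
  inj0 <- injection_spec(needle_depth_mm = 0)
  tip0 <- needle_tip_position(inj0, dom)
  pc <- polar_convert(rbind(tip0[1:2]), dom$params$mx)
  expect_lt(abs(pc[, "r_mm"] - limacon_radius(dom$params, pc[, "phi_hat"])),
            1e-6)

  # standard pars plana injection: strictly interior, > 1 mm off the retina
  tip <- needle_tip_position(injection_spec(), dom)
  rel <- c(tip[1] - dom$params$mx, sqrt(tip[2]^2 + tip[3]^2))
  r <- sqrt(sum(rel^2))
  Rb <- limacon_radius(dom$params, acos(rel[1] / r))
  expect_gt(Rb - r, 1)

  # central injection reaches the middle of the vitreous
  ctr <- colMeans(fx("mesh3")$vert) * 1e3
  tipc <- needle_tip_position(injection_positions()$center, dom)
  expect_lt(sqrt(sum((tipc - ctr)^2)), 2)

  # an over-deep needle is rejected with a distance report
  expect_error(needle_tip_position(injection_spec(needle_depth_mm = 40), dom),
               "outside the vitreous")
})

test_that("head orientations map to the documented gravity directions", {
  expect_equal(head_orientation_to_gravity("standing"), c(0, 0, -1))
  expect_equal(head_orientation_to_gravity("back"), c(1, 0, 0))
  expect_equal(head_orientation_to_gravity("left"), c(0, -1, 0))
  expect_equal(head_orientation_to_gravity("right"), c(0, 1, 0))
  expect_error(head_orientation_to_gravity("prone"), "unknown")

  sch <- alternating_schedule(c("standing", "back"), 12 * 3600, 86400)
  expect_length(sch$segments, 2)
  expect_equal(sch$segments[[1]]$duration_s, 43200)
  expect_error(alternating_schedule(c("standing"), 10000, 86400))
})

test_that("scenario runs are deterministic and dose-invariant", {
  cfg <- scenario_config(h_mm = 1.8, horizon_days = 4, label = "det")
  mesh <- build_mesh(build_domain(cfg$geometry, cfg$spec), h = cfg$h_mm)
  flow <- solve_darcy(assemble_darcy(mesh, cfg$fp))
  r1 <- run_scenario(cfg, mesh = mesh, flow = flow)
  r2 <- run_scenario(cfg, mesh = mesh, flow = flow)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_functional_csv(r1$run$series, file.path(d1, "f.csv"))
  write_functional_csv(r2$run$series, file.path(d2, "f.csv"))
  expect_identical(unname(tools::md5sum(file.path(d1, "f.csv"))),
                   unname(tools::md5sum(file.path(d2, "f.csv"))))

  cfg2 <- cfg
  cfg2$injection$dose_kg <- 2 * cfg$injection$dose_kg
  r3 <- run_scenario(cfg2, mesh = mesh, flow = flow)
  expect_close(r3$summary$J_omega_T, r1$summary$J_omega_T, 1e-10)
  expect_close(r3$summary$J_M_omega_T, r1$summary$J_M_omega_T, 1e-10)
  expect_close(r3$summary$J_R_T, r1$summary$J_R_T, 1e-10)
  expect_equal(r3$summary$peak_J_M / r1$summary$peak_J_M, 2, tolerance = 1e-9)
})

test_that("with flow off the macular peak time follows r^2/(6D)", {
  mesh <- fx("ax_mesh_fine")
  D <- 4e-11
  C0 <- make_initial_bolus(mesh, c(4, 0, 0), 1.5, 1e-6)
  r <- advance(C0, NULL, transport_params(D = D),
               theta_scheme(0.125 * 86400), 8 * 86400, mesh = mesh,
               audit = FALSE)
  dist <- (12 - 4) * 1e-3    # bolus centre to macula centre
  t_formula <- dist^2 / (6 * D) / 86400
  expect_lt(abs(r$peak_time_days - t_formula) / t_formula, 0.3)
})

test_that("mirroring the injection across the meridian plane leaves the
           functionals unchanged when gravity is off", {
  mesh <- fx("mesh3")
  flow <- fx("flow3")
  tp <- transport_params()
  tip <- needle_tip_position(injection_spec(psi_z_deg = 70), fx("dom"))
  expect_gt(abs(tip[3]), 0.1)   # genuinely out of plane
  C1 <- make_initial_bolus(mesh, tip, 2.29, 1.25e-6)
  C2 <- make_initial_bolus(mesh, tip * c(1, 1, -1), 2.29, 1.25e-6)
  r1 <- advance(C1, flow, tp, theta_scheme(), 6 * 86400, mesh = mesh,
                audit = FALSE)
  r2 <- advance(C2, flow, tp, theta_scheme(), 6 * 86400, mesh = mesh,
                audit = FALSE)
  for (cc in c("J_omega", "J_M_omega_cum", "J_R"))
    expect_lt(max(abs(r1$series[[cc]] - r2$series[[cc]])) /
                max(abs(r1$series[[cc]]) + 1e-300), 0.01)
  expect_lt(max(abs(r1$series$J_M - r2$series$J_M)) / max(r1$series$J_M),
            0.01)
})

test_that("without settling every head orientation gives the same run", {
  mesh <- fx("ax_mesh")
  flow <- fx("flow_ax")
  tp <- transport_params(v_settle = 0)
  C0 <- make_initial_bolus(mesh, c(0.5, 0, 0), 2.29, 1.25e-6)
  base <- advance(C0, flow, tp, theta_scheme(), 4 * 86400, mesh = mesh,
                  audit = FALSE)
  sch <- alternating_schedule(c("standing", "back"), 43200, 4 * 86400)
  alt <- advance(C0, flow, tp, theta_scheme(), 4 * 86400, mesh = mesh,
                 schedule = sch, audit = FALSE)
  expect_identical(alt$series$J_omega, base$series$J_omega)
  expect_identical(alt$series$J_M, base$series$J_M)
})

test_that("sweeps report zero self-differences and reject mismatched horizons", {
  cfg <- scenario_config(h_mm = 1.8, horizon_days = 3, label = "a")
  cfg2 <- cfg; cfg2$label <- "b"
  sw <- sweep_scenarios(list(cfg, cfg2), baseline = "a")
  expect_close(unlist(sw$table[, grep("^rel_", names(sw$table))]), 0, 1e-12)
  cfg3 <- scenario_config(h_mm = 1.8, horizon_days = 5, label = "c")
  expect_error(sweep_scenarios(list(cfg, cfg3)), "horizons")
})

test_that("axisymmetric mode refuses symmetry-breaking scenarios", {
  expect_error(scenario_config(mode = "axisymmetric-2d"),
               "symmetry")   # standard injection is off-axis
  expect_error(scenario_config(mode = "axisymmetric-2d",
                               injection = injection_spec(psi_z_deg = 120)),
               "symmetry")
  # an on-axis central injection is fine
  expect_s3_class(scenario_config(mode = "axisymmetric-2d",
                                  injection = injection_positions()$center),
                  "scenario_config")
})
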