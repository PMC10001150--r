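test_that("effective velocity composes flow and settling as stated", {
  tp0 <- transport_params(v_settle = 0)
  v0 <- effective_velocity(NULL, tp0)
  expect_equal(v0(1:3, matrix(0, 3, 3)), matrix(0, 3, 3))

  tps <- transport_params(v_settle = 1e-8, gravity_dir = c(0, 0, -1))
  vs <- effective_velocity(NULL, tps)
  expect_equal(vs(1:2, matrix(1, 2, 3)),
               matrix(c(0, 0, 0, 0, -1e-8, -1e-8), 2, 3))
  expect_warning(effective_velocity(NULL, tps, gravity_dir = c(0, 0, -2)),
                 "normalis")

  # Stokes settling closed form: 2 drho g a^2 / (9 mu)
  expect_equal(stokes_settling_speed(5e-9, drho = 350, mu = 6.9e-4, g = 9.81),
               2 * 350 * 9.81 * 25e-18 / (9 * 6.9e-4))
})

test_that("theta scheme constants give one shared sub-step matrix", {
  s <- theta_scheme()
  expect_equal(s$theta, 1 - sqrt(2) / 2, tolerance = 1e-15)
  expect_equal(s$alpha * s$theta, (1 - s$alpha) * (1 - 2 * s$theta),
               tolerance = 1e-15)
  expect_error(theta_scheme(-1))
})

test_that("initial bolus carries the exact dose and bounded support", {
  mesh <- fx("ax_mesh_fine")
  mv <- eyevit:::p1_massvec(mesh)
  C0 <- make_initial_bolus(mesh, c(0.5, 0, 0), 2.4, 2e-6, mv)
  expect_equal(sum(mv * C0), 2e-6, tolerance = 1e-12)
  dist <- sqrt(rowSums((mesh$vert - matrix(c(0.5e-3, 0), nrow(mesh$vert), 2,
                                           byrow = TRUE))^2))
  expect_true(all(C0[dist > (2.4 + mesh$h_mm) * 1e-3] == 0))
  expect_error(make_initial_bolus(mesh, c(25, 0, 0), 2, 1e-6, mv),
               "outside the vitreous")

  # the raw (pre-normalisation) quadrature of the mollified ball is close
  # to the analytic volume and improves under refinement
  vol_of <- function(m) {
    mv <- eyevit:::p1_massvec(m)
    dist <- sqrt(rowSums((m$vert - matrix(c(0.5e-3, 0), nrow(m$vert), 2,
                                          byrow = TRUE))^2))
    ramp <- 0.5 * m$h_mm * 1e-3
    sum(mv * pmin(1, pmax(0, (2.4e-3 - dist) / ramp + 0.5)))
  }
  vex <- (4 / 3) * pi * 2.4e-3^3
  e1 <- abs(vol_of(fx("ax_mesh")) / vex - 1)
  e2 <- abs(vol_of(fx("ax_mesh_fine")) / vex - 1)
  expect_lt(e2, 0.05)
  expect_lt(e2, e1)
})

test_that("a closed system conserves mass and D=0, v=0 gives identity dynamics", {
  dom <- build_domain(default_eye_params(), boundary_spec(0, 0))  # all retina
  mesh <- build_mesh(dom, h = 1.3, mode = "axisymmetric-2d")
  tp <- transport_params(D = 4e-11, P = 0)
  ops <- assemble_transport(mesh, NULL, tp)
  expect_length(ops$dir_nodes, 0)
  # column sums of the closed operator vanish (semi-discrete conservation)
  expect_lt(max(abs(Matrix::colSums(ops$A))), 1e-12 * max(abs(ops$A)))
  C0 <- make_initial_bolus(mesh, c(2, 0, 0), 2, 1e-6, ops$massvec)
  C1 <- fractional_theta_step(C0, ops, theta_scheme(), 0)
  expect_lt(abs(sum(ops$massvec * C1) / sum(ops$massvec * C0) - 1), 1e-12)

  ops0 <- assemble_transport(mesh, NULL, transport_params(D = 0, P = 0))
  C1 <- fractional_theta_step(C0, ops0, theta_scheme(), 0)
  expect_close(as.numeric(C1), C0, 1e-14 * max(C0))
})

test_that("retinal Robin block matches a per-facet quadrature oracle", {
  mesh <- fx("ax_mesh")
  tp0 <- transport_params(P = 0)
  tpP <- transport_params(P = 3e-8)
  R <- assemble_transport(mesh, NULL, tpP, mass = "consistent")$A -
    assemble_transport(mesh, NULL, tp0, mass = "consistent")$A
  # oracle: per retina edge, int pi*|y| P lambda_l lambda_m dl by 2-pt Gauss
  ret <- eyevit:::marked_facets(mesh, 1L)
  nv <- nrow(mesh$vert)
  Rq <- matrix(0, nv, nv)
  gs <- 0.5 / sqrt(3)
  for (e in ret) {
    a <- mesh$vert[mesh$facet[e, 1], ]; b <- mesh$vert[mesh$facet[e, 2], ]
    len <- mesh$facet_area[e]
    for (s in c(0.5 - gs, 0.5 + gs)) {
      x <- a * (1 - s) + b * s
      lam <- c(1 - s, s)
      idx <- mesh$facet[e, ]
      Rq[idx, idx] <- Rq[idx, idx] +
        0.5 * len * pi * abs(x[2]) * 3e-8 * outer(lam, lam)
    }
  }
  expect_lt(max(abs(R - Rq)), 1e-12 * max(Rq))
})

test_that("hyaloid nodes stay exactly at the boundary value", {
  mesh <- fx("ax_mesh")
  flow <- fx("flow_ax")
  tp <- transport_params()
  ops <- assemble_transport(mesh, flow, tp)
  C0 <- make_initial_bolus(mesh, c(-2, 0, 0), 2.29, 1.25e-6, ops$massvec)
  C <- C0
  for (i in 1:3) C <- as.numeric(fractional_theta_step(C, ops, theta_scheme(), 0))
  expect_true(all(C[ops$dir_nodes] == 0))
})

test_that("the theta scheme shows second-order decay against the ODE oracle", {
  lam <- c(3, 0.5)
  ops1 <- list(M = Matrix::Diagonal(2), A = Matrix::Diagonal(x = lam),
               dir_nodes = integer(0), source = NULL,
               cache = new.env(parent = emptyenv()))
  errs <- vapply(c(0.1, 0.05, 0.025, 0.0125), function(dt) {
    s <- theta_scheme(dt_macro = dt, first_day_halved = FALSE)
    u <- c(1, 1); t <- 0
    while (t < 1 - 1e-12) {
      u <- fractional_theta_step(u, ops1, s, t, dt)
      t <- t + dt
    }
    max(abs(u - exp(-lam)))
  }, 0)
  orders <- diff(log(errs)) / log(0.5)
  expect_true(all(orders > 1.9 & orders < 2.1))
})

test_that("a free bolus follows the analytic ball-source diffusion kernel", {
  # uniform ball of radius a diffusing in free space:
  # C(r,t)/C0 = (erf((a-r)/s) + erf((a+r)/s))/2
  #           + s/(2 r sqrt(pi)) (exp(-((a+r)/s)^2) - exp(-((a-r)/s)^2)),
  # s = sqrt(4 D t); boundary effects negligible at 1 day for D = 4e-11
  mesh <- build_mesh(fx("dom_circle"), h = 0.35, mode = "axisymmetric-2d")
  a <- 1.5e-3
  D <- 4e-11
  dist <- sqrt(rowSums(mesh$vert^2))
  # mollified unit-concentration ball with the exact ball mass, so the
  # far-field amplitude of the kernel comparison is unbiased
  C0 <- make_initial_bolus(mesh, c(0, 0, 0), a * 1e3,
                           dose = (4 / 3) * pi * a^3)
  tp <- transport_params(D = D, P = 0)
  ops <- assemble_transport(mesh, NULL, tp)
  sch <- theta_scheme(dt_macro = 0.025 * 86400, first_day_halved = FALSE)
  C <- C0; t <- 0
  for (i in 1:40) { C <- as.numeric(fractional_theta_step(C, ops, sch, t, sch$dt_macro)); t <- t + sch$dt_macro }
  s <- sqrt(4 * D * t)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  r <- pmax(dist, 1e-6)
  Cex <- (erf((a - r) / s) + erf((a + r) / s)) / 2 +
    s / (2 * r * sqrt(pi)) * (exp(-((a + r) / s)^2) - exp(-((a - r) / s)^2))
  sel <- dist < 5e-3
  expect_lt(max(abs(C[sel] - Cex[sel])), 0.03 * max(Cex))
})

test_that("runs are monotone in total drug, bounded at 10x the macro step,
           and keep the Galerkin undershoot within half a percent", {
  mesh <- fx("mesh3")
  flow <- fx("flow3")
  tp <- transport_params()
  tip <- needle_tip_position(injection_spec(), fx("dom"))
  C0 <- make_initial_bolus(mesh, tip, 2.29, 1.25e-6)
  r <- advance(C0, flow, tp, theta_scheme(), 6 * 86400, mesh = mesh,
               store_states = TRUE)
  expect_true(all(diff(r$series$J_omega) <= 1e-12))
  expect_gt(min(vapply(r$states, min, 0)), -0.005 * max(C0))

  r10 <- advance(C0, flow, tp, theta_scheme(2.5 * 86400, FALSE), 30 * 86400,
                 mesh = mesh, audit = FALSE)
  expect_lt(max(abs(r10$C_final)), 1.05 * max(C0))
})

test_that("axisymmetric and full-3d runs agree for an on-axis scenario", {
  # central injection, gravity off: the problem is rotationally symmetric
  dom <- fx("dom")
  tp <- transport_params()
  horizon <- 10 * 86400
  region <- macula_region(dom$macula_center_mm, 2)

  m2 <- fx("ax_mesh")
  f2 <- fx("flow_ax")
  C2 <- make_initial_bolus(m2, c(0.5, 0, 0), 2.29, 1.25e-6)
  r2 <- advance(C2, f2, tp, theta_scheme(), horizon, mesh = m2,
                region = region, audit = FALSE)

  m3 <- fx("mesh3")
  f3 <- fx("flow3")
  C3 <- make_initial_bolus(m3, c(0.5, 0, 0), 2.29, 1.25e-6)
  r3 <- advance(C3, f3, tp, theta_scheme(), horizon, mesh = m3,
                region = region, audit = FALSE)

  jm2 <- r2$series$J_M / r2$mass0
  jm3 <- r3$series$J_M / r3$mass0
  expect_lt(max(abs(jm2 - jm3)) / max(jm3), 0.05)
})

test_that("anisotropic diffusion accepts SPD tensors only and axisymmetric
           mode refuses symmetry-breaking settings", {
  expect_error(transport_params(D = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "positive definite")
  Dt <- diag(c(4e-11, 2e-11, 2e-11))
  tp <- transport_params(D = Dt)
  expect_silent(assemble_transport(fx("mesh3"), NULL, tp))
  expect_error(assemble_transport(fx("ax_mesh"), NULL, tp), "full-3d")
  tpg <- transport_params(v_settle = 1e-9, gravity_dir = c(0, 0, -1))
  expect_error(assemble_transport(fx("ax_mesh"), NULL, tpg), "optic axis")
})
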