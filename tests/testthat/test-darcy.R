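test_that("element matrices match a per-element quadrature oracle", {
  set.seed(3)
  vert <- matrix(rnorm(12), 4, 3)
  cell <- matrix(1:4, 1, 4)
  vol <- eyevit:::tet_volumes(vert, cell)
  if (vol < 0) { cell[, 3:4] <- cell[, c(4, 3)]; vol <- abs(vol) }
  fb <- eyevit:::build_facets(cell, 4L, 3L)
  p1 <- vert[fb$facet[, 1], ]; p2 <- vert[fb$facet[, 2], ]; p3 <- vert[fb$facet[, 3], ]
  cr <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
              (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
              (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  area <- 0.5 * sqrt(rowSums(cr^2))
  mesh <- list(dim = 3L, cell = cell, vert = vert, vol = vol, facet = fb$facet,
               cell_facet = fb$cell_facet, cell_facet_sign = matrix(1, 1, 4),
               facet_area = area)
  fp <- list(mu = 2, kappa = 0.5)
  core <- eyevit:::assemble_darcy_core(mesh, fp)
  # oracle: 4-point degree-2 quadrature of the flux-normalised RT0 basis
  r <- eyevit:::quad_tet4
  Mq <- matrix(0, 4, 4)
  for (q in 1:4) {
    x <- colSums(r$bary[q, ] * vert)
    for (l in 1:4) for (m in 1:4) {
      phl <- (x - vert[l, ]) / (3 * vol)
      phm <- (x - vert[m, ]) / (3 * vol)
      Mq[l, m] <- Mq[l, m] + (fp$mu / fp$kappa) * r$w[q] * vol * sum(phl * phm)
    }
  }
  fid <- mesh$cell_facet[1, ]
  expect_close(as.matrix(core$M)[fid, fid], Mq, 1e-12 * max(abs(Mq)))
  expect_equal(as.numeric(core$B)[fid], rep(-1, 4))  # int_K div phi_i = sigma_i
})

test_that("velocity mass block is symmetric and the rest state is exact", {
  sys <- assemble_darcy(fx("ax_mesh"))
  expect_lt(max(abs(sys$M - Matrix::t(sys$M))) / max(abs(sys$M)), 1e-12)

  # no driving force: v = 0 and p = Pv everywhere
  sys0 <- assemble_darcy(fx("ax_mesh"), inflow = function(x) rep(0, nrow(x)))
  f0 <- solve_darcy(sys0)
  expect_lt(max(abs(f0$V)), 1e-18)
  expect_close(f0$P, rep(flow_params()$Pv, length(f0$P)), 1e-6)
  expect_equal(divergence_check(f0), 0, tolerance = 1e-15)
})

test_that("Poiseuille inflow profile matches its closed form and band check", {
  dom <- fx("dom")
  ring <- eyevit:::hyaloid_ring(dom)
  ctr <- ring$center_mm * 1e-3
  Rp <- ring$R_pflow_mm * 1e-3
  cp <- 2.5
  # at the ring centre the speed is c * R^2; at distance R it vanishes
  expect_equal(poiseuille_inflow(cbind(ctr[1], ctr[2], 0), dom, cp),
               cp * Rp^2)
  along <- ctr + c(0, Rp)
  expect_equal(poiseuille_inflow(cbind(along[1], along[2], 0), dom, cp), 0,
               tolerance = 1e-18)
  expect_equal(poiseuille_inflow(cbind(ctr[1], ctr[2] + 2 * Rp, 0), dom, cp), 0)
  expect_error(poiseuille_inflow(cbind(12e-3, 0, 0), dom, cp, check = TRUE),
               "hyaloid")
})

test_that("calibrated influx reproduces the target through-flow", {
  mesh <- build_mesh(fx("dom"), h = 0.5, mode = "axisymmetric-2d")
  sys <- assemble_darcy(mesh)
  hy <- eyevit:::marked_facets(mesh, 3L)
  ybar <- abs(mesh$vert[mesh$facet[hy, 1], 2] +
                mesh$vert[mesh$facet[hy, 2], 2]) / 2
  Qd <- -sum(pi * ybar * sys$vfix[hy])
  expect_lt(abs(Qd / attr(sys$fp, "Q_target") - 1), 0.005)
})

test_that("Darcy pressure matches the concentric-spheres analytic solution", {
  R2 <- 10; R1 <- 4
  dom <- build_domain(limacon_params(R2), boundary_spec(0, 0))
  msh <- build_mesh(dom, h = 0.5, mode = "axisymmetric-2d", rho_min = R1 / R2)
  fp <- calibrate_inflow(dom, flow_params())
  u0 <- 1e-7
  Q <- 4 * pi * (R1 * 1e-3)^2 * u0
  fl <- solve_darcy(assemble_darcy(msh, fp, inflow = function(x) rep(u0, nrow(x))))
  pR2 <- fp$Pv + (fp$L / fp$K_RCS) * Q / (4 * pi * (R2 * 1e-3)^2)
  A <- pR2 - fp$mu * Q / (4 * pi * fp$kappa * (R2 * 1e-3))
  cent <- (msh$vert[msh$cell[, 1], ] + msh$vert[msh$cell[, 2], ] +
             msh$vert[msh$cell[, 3], ]) / 3
  r <- sqrt(rowSums(cent^2))
  pex <- A + fp$mu * Q / (4 * pi * fp$kappa * r)
  w <- msh$weights * msh$vol
  err <- sqrt(sum(w * (fl$P - pex)^2) / sum(w * (pex - fp$Pv)^2))
  expect_lt(err, 0.01)
})

test_that("solved eye flow balances mass, respects the lens and bounds pressure", {
  fl <- fx("flow3")
  mesh <- fl$mesh
  bf <- boundary_flux(fl)
  expect_lt(abs(bf[["retina"]] + bf[["hyaloid"]]) / abs(bf[["retina"]]), 1e-8)
  peak_in <- max(abs(fl$V[eyevit:::marked_facets(mesh, 3L)]))
  expect_lt(max(abs(fl$V[eyevit:::marked_facets(mesh, 2L)])), 1e-10 * peak_in)
  expect_gte(min(fl$P), fl$fp$Pv - 1e-6)
  expect_lt(divergence_check(fl), 1e-10 * max(flow_speed(fl)) / (mesh$h_mm * 1e-3))
})

test_that("flow responds linearly to the inflow strength", {
  mesh <- fx("ax_mesh")
  fp1 <- calibrate_inflow(mesh$domain, flow_params())
  fp2 <- fp1
  fp2$c_pflow <- 2 * fp1$c_pflow
  f1 <- solve_darcy(assemble_darcy(mesh, fp1))
  f2 <- solve_darcy(assemble_darcy(mesh, fp2))
  expect_close(f2$V, 2 * f1$V, 1e-6 * max(abs(f1$V)))
  expect_close(f2$P - fp1$Pv, 2 * (f1$P - fp1$Pv),
               1e-6 * max(abs(f1$P - fp1$Pv)))
})

test_that("Schur-complement CG agrees with the direct saddle factorization", {
  mesh <- build_mesh(fx("dom"), h = 1.3, mode = "axisymmetric-2d")
  sys <- assemble_darcy(mesh)
  f1 <- solve_darcy(sys)
  f2 <- solve_darcy(sys, method = "direct")
  expect_lt(max(abs(f1$P - f2$P)) / max(abs(f2$P - sys$fp$Pv)), 1e-8)
  expect_lt(max(abs(f1$V - f2$V)) / max(abs(f2$V)), 1e-7)
})
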