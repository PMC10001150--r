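#' Physical parameters of the aqueous-humor Darcy flow
#'
#' None of these values is patient-measurable from the ultrasound data;
#' they are literature-sourced defaults (provenance in the comments of
#' `inst/extdata/default_params.yaml` and in the methods vignette):
#' * `kappa` 6.9e-15 m^2 -- vitreous Darcy permeability; with `mu` gives
#'   a hydraulic conductivity kappa/mu = 1e-11 m^2/(Pa s), i.e. a
#'   pressure drop of a few Pa across the vitreous at physiological
#'   through-flow.
#' * `mu` 6.9e-4 Pa s -- aqueous humor viscosity at 37 C (close to water).
#' * `Pv` 1200 Pa (9 mmHg) -- episcleral venous pressure.
#' * `K_RCS` 4.5e-15 m^2/(Pa s), `L` 1e-3 m -- lumped
#'   retina-choroid-sclera conductance K_RCS/L = 4.5e-12 m/(Pa s),
#'   consistent with a transretinal pressure difference of a few hundred
#'   Pa at the default through-flow.
#' * `aqueous_production` 2.5 uL/min and `vitreous_fraction` 0.1 -- the
#'   portion of aqueous production that percolates the vitreous; these
#'   calibrate the inflow strength `c_pflow` (see [calibrate_inflow()]).
#'
#' @param kappa hydraulic permeability, m^2.
#' @param mu dynamic viscosity, Pa s.
#' @param Pv episcleral pressure, Pa.
#' @param K_RCS total hydraulic conductivity of retina-choroid-sclera,
#'   m^2/(Pa s); the Robin condition uses the quotient `K_RCS/L`.
#' @param L retinal thickness, m.
#' @param aqueous_production aqueous humor production, m^3/s.
#' @param vitreous_fraction fraction of production routed through the
#'   vitreous.
#' @param c_pflow inflow strength 1/(m s); `NULL` means calibrate from
#'   the target through-flow.
#' @export
flow_params <- function(kappa = 6.9e-15, mu = 6.9e-4, Pv = 1200,
                        K_RCS = 4.5e-15, L = 1e-3,
                        aqueous_production = 2.5e-9 / 60,
                        vitreous_fraction = 0.1, c_pflow = NULL) {
  p <- list(kappa = kappa, mu = mu, Pv = Pv, K_RCS = K_RCS, L = L,
            aqueous_production = aqueous_production,
            vitreous_fraction = vitreous_fraction, c_pflow = c_pflow)
  num <- unlist(p[c("kappa", "mu", "Pv", "K_RCS", "L",
                    "aqueous_production", "vitreous_fraction")])
  if (!all(is.finite(num)) || any(num <= 0))
    stop("flow parameters must be finite and strictly positive")
  structure(p, class = "flow_params")
}

# Hyaloid inflow geometry: the "central circular ring" between lens and
# retina is the circle of revolution through the midpoint of the
# hyaloid band; R_pflow is half the meridian chord between the band's
# lens edge and retina edge.
hyaloid_ring <- function(domain) {
  spec <- domain$spec
  lens_lo <- pi - spec$lens_half * pi / 180
  hy_lo <- lens_lo - spec$hyaloid_width * pi / 180
  mid <- (lens_lo + hy_lo) / 2
  pm <- profile_point(domain$params, mid)[1, ]
  pa <- profile_point(domain$params, lens_lo)[1, ]
  pb <- profile_point(domain$params, hy_lo)[1, ]
  list(center_mm = c(pm[["x_mm"]], pm[["y_mm"]]),
       R_pflow_mm = 0.5 * sqrt(sum((pa - pb)^2)),
       band = c(hy_lo, lens_lo))
}

#' Poiseuille inflow profile on the hyaloid band
#'
#' Inflow speed `c_pflow * (R_pflow^2 - r_pflow^2)` where `r_pflow` is
#' the 3d distance from the evaluation point to the central circular
#' ring between lens and retina, clamped to zero outside the band.
#' Positive values are directed into the domain.
#'
#' @param x points, n x 3 (or n x 2 meridian) matrix in metres.
#' @param domain the [build_domain()] geometry.
#' @param c_pflow inflow strength, 1/(m s).
#' @param check reject points whose polar angle is outside the hyaloid
#'   band (with a small tolerance).
#' @return inflow normal speed(s), m/s.
#' @export
poiseuille_inflow <- function(x, domain, c_pflow, check = FALSE) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  ring <- hyaloid_ring(domain)
  y_ax <- if (ncol(x) >= 3) sqrt(x[, 2]^2 + x[, 3]^2) else abs(x[, 2])
  if (check) {
    rel <- cbind(x[, 1] - domain$params$mx * MM, y_ax)
    ph <- acos(pmin(1, pmax(-1, rel[, 1] / sqrt(rowSums(rel^2)))))
    band <- ring$band
    tolr <- 0.05
    if (any(ph < band[1] - tolr | ph > band[2] + tolr))
      stop("position is not on the hyaloid boundary")
  }
  # distance to the ring: meridian-plane distance to the ring's profile point
  d2 <- (x[, 1] - ring$center_mm[1] * MM)^2 + (y_ax - ring$center_mm[2] * MM)^2
  Rp <- ring$R_pflow_mm * MM
  pmax(c_pflow * (Rp^2 - d2), 0)
}

#' Calibrate the inflow strength to a target through-flow
#'
#' Chooses `c_pflow` so that the analytic surface integral of the
#' Poiseuille profile over the revolved hyaloid band equals the target
#' vitreous through-flow `aqueous_production * vitreous_fraction`
#' (Gauss-Legendre quadrature along the band).
#'
#' @param domain geometry.
#' @param fp a [flow_params()].
#' @return `fp` with `c_pflow` set (and `R_pflow_mm` attached).
#' @export
calibrate_inflow <- function(domain, fp = flow_params()) {
  ring <- hyaloid_ring(domain)
  gl <- statmod_gauss(48)
  a <- ring$band[1]; b <- ring$band[2]
  phi <- a + (b - a) * gl$nodes
  w <- (b - a) * gl$weights
  p <- profile_point(domain$params, phi) * MM
  eps <- 1e-7
  pp <- (profile_point(domain$params, phi + eps) -
           profile_point(domain$params, phi - eps)) / (2 * eps) * MM
  dl <- sqrt(rowSums(pp^2))
  prof <- poiseuille_inflow(p, domain, c_pflow = 1)
  I <- sum(w * prof * 2 * pi * abs(p[, 2]) * dl)
  Q <- fp$aqueous_production * fp$vitreous_fraction
  fp$c_pflow <- Q / I
  attr(fp, "R_pflow_mm") <- ring$R_pflow_mm
  attr(fp, "Q_target") <- Q
  fp
}

# Gauss-Legendre on [0,1]
statmod_gauss <- function(n) {
  # Golub-Welsch via symmetric tridiagonal eigen-decomposition
  i <- seq_len(n - 1)
  bsub <- i / sqrt(4 * i^2 - 1)
  E <- eigen(diag(0, n) + rbind(cbind(0, diag(bsub, n - 1)), 0) +
               t(rbind(cbind(0, diag(bsub, n - 1)), 0)), symmetric = TRUE)
  x <- E$values
  w <- 2 * E$vectors[1, ]^2
  o <- order(x)
  list(nodes = (x[o] + 1) / 2, weights = w[o] / 2)
}

# RT0 velocity mass matrix (with Robin boundary augmentation) and
# divergence coupling for the mixed Darcy system.
#
# dof i = facet flux int_f v.n dS (3d) or int_e v.n dl (axisym), with n
# the stored facet normal (outward from facet_cell[,1], outward from the
# domain on the boundary).
assemble_darcy_core <- function(mesh, fp) {
  d <- mesh$dim
  nc <- nrow(mesh$cell)
  nf <- nrow(mesh$facet)
  vert <- mesh$vert
  cell <- mesh$cell
  sgn <- mesh$cell_facet_sign
  fid <- mesh$cell_facet
  Sf <- matrix(mesh$facet_area[fid], nc, d + 1L)
  mu_over_k <- fp$mu / fp$kappa

  if (d == 3L) {
    A <- lapply(1:4, function(l) vert[cell[, l], , drop = FALSE])
    Ssum <- A[[1]] + A[[2]] + A[[3]] + A[[4]]
    xb <- Ssum / 4
    dots <- function(u, v) rowSums(u * v)
    SS <- dots(Ssum, Ssum)
    sq <- dots(A[[1]], A[[1]]) + dots(A[[2]], A[[2]]) +
      dots(A[[3]], A[[3]]) + dots(A[[4]], A[[4]])
    vol <- mesh$vol
    ii <- jj <- vv <- vector("list", 16L)
    n <- 0L
    for (l in 1:4) for (m in 1:4) {
      G <- vol * ((SS + sq) / 20 - dots(xb, A[[l]] + A[[m]]) + dots(A[[l]], A[[m]]))
      val <- mu_over_k * sgn[, l] * sgn[, m] / (9 * vol^2) * G
      n <- n + 1L
      ii[[n]] <- fid[, l]; jj[[n]] <- fid[, m]; vv[[n]] <- val
    }
    M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                              dims = c(nf, nf))
    Bi <- as.vector(fid)
    Bj <- rep(seq_len(nc), d + 1L)
    Bx <- as.vector(-sgn)
    B <- Matrix::sparseMatrix(i = Bi, j = Bj, x = Bx, dims = c(nf, nc))
  } else {
    # axisymmetric: weight pi*|y| over the full meridian mesh
    A <- lapply(1:3, function(l) vert[cell[, l], , drop = FALSE])
    vol <- mesh$vol
    rule <- quad_tri6
    qp <- simplex_quad_points(vert, cell, rule)
    ii <- jj <- vv <- vector("list", 9L)
    n <- 0L
    for (l in 1:3) for (m in 1:3) {
      acc <- 0
      for (q in seq_along(rule$w)) {
        x <- qp[[q]]
        wgt <- pi * abs(x[, 2]) * rule$w[q] * vol
        phil <- (x - A[[l]]) * (sgn[, l] / (2 * vol))
        phim <- (x - A[[m]]) * (sgn[, m] / (2 * vol))
        acc <- acc + wgt * rowSums(phil * phim)
      }
      n <- n + 1L
      ii[[n]] <- fid[, l]; jj[[n]] <- fid[, m]; vv[[n]] <- mu_over_k * acc
    }
    M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                              dims = c(nf, nf))
    # B[e, K] = -sigma * pi * |y_bar_e| (v.n = V_e / l_e, weighted edge flux)
    ybar <- abs(vert[mesh$facet[, 1], 2] + vert[mesh$facet[, 2], 2]) / 2
    Bx <- as.vector(-sgn * matrix(pi * ybar[fid], nc, d + 1L))
    B <- Matrix::sparseMatrix(i = as.vector(fid), j = rep(seq_len(nc), d + 1L),
                              x = Bx, dims = c(nf, nc))
  }
  list(M = M, B = B)
}

#' Assemble the mixed Darcy saddle-point system
#'
#' Lowest-order Raviart-Thomas velocity / piecewise-constant pressure
#' discretization of the Darcy model with
#' no-flux lens (essential), prescribed Poiseuille influx on the
#' hyaloid (essential) and the retinal Robin relation
#' `n.v = K_RCS (p - Pv) / L` entering the boundary terms.
#'
#' @param mesh an `eye_mesh` with complete boundary markers.
#' @param fp [flow_params()]; `c_pflow` is calibrated from the geometry
#'   if unset.
#' @param inflow optional override: function mapping an n x dim matrix
#'   of facet points (metres) to inflow speeds (m/s, positive into the
#'   domain) on marker-3 facets.  Default is the Poiseuille profile.
#' @return A `darcy_system` (blocks `M`, `B`, right-hand side, fixed
#'   velocity dofs and values).
#' @export
assemble_darcy <- function(mesh, fp = flow_params(), inflow = NULL) {
  stopifnot(inherits(mesh, "eye_mesh"))
  if (anyNA(mesh$marker[mesh$boundary])) stop("boundary markers incomplete")
  if (is.null(fp$c_pflow)) fp <- calibrate_inflow(mesh$domain, fp)
  core <- assemble_darcy_core(mesh, fp)
  nf <- nrow(mesh$facet)
  d <- mesh$dim
  Fv <- numeric(nf)
  Mdiag_add <- numeric(nf)
  ret <- marked_facets(mesh, 1L)
  LK <- fp$L / fp$K_RCS
  # the solve works with the gauge-shifted pressure p - Pv, for which the
  # Robin right-hand side vanishes; Pv is added back in solve_darcy
  if (d == 3L) {
    Mdiag_add[ret] <- LK / mesh$facet_area[ret]
  } else {
    ybar <- abs(mesh$vert[mesh$facet[, 1], 2] + mesh$vert[mesh$facet[, 2], 2]) / 2
    Mdiag_add[ret] <- LK * pi * ybar[ret] / mesh$facet_area[ret]
  }
  M <- core$M + Matrix::Diagonal(nf, Mdiag_add)
  # essential dofs
  lens <- marked_facets(mesh, 2L)
  hyal <- marked_facets(mesh, 3L)
  fixed <- logical(nf)
  fixed[lens] <- TRUE
  fixed[hyal] <- TRUE
  vfix <- numeric(nf)
  if (length(hyal)) {
    speed_fun <- if (is.null(inflow))
      function(x) poiseuille_inflow(x, mesh$domain, fp$c_pflow) else inflow
    vfix[hyal] <- -facet_integral(mesh, hyal, speed_fun)   # inward flux < 0
  }
  structure(list(M = M, B = core$B, F = Fv, fixed = fixed, vfix = vfix,
                 pressure_shift = fp$Pv, mesh = mesh, fp = fp),
            class = "darcy_system")
}

# int_f g dS by a degree-2 rule (3d facets: mid-edge; edges: 2-pt Gauss);
# the RT0 dof is the unweighted facet integral in both modes.
facet_integral <- function(mesh, facets, g) {
  if (mesh$dim == 3L) {
    p1 <- mesh$vert[mesh$facet[facets, 1], , drop = FALSE]
    p2 <- mesh$vert[mesh$facet[facets, 2], , drop = FALSE]
    p3 <- mesh$vert[mesh$facet[facets, 3], , drop = FALSE]
    (g((p1 + p2) / 2) + g((p2 + p3) / 2) + g((p1 + p3) / 2)) / 3 *
      mesh$facet_area[facets]
  } else {
    p1 <- mesh$vert[mesh$facet[facets, 1], , drop = FALSE]
    p2 <- mesh$vert[mesh$facet[facets, 2], , drop = FALSE]
    s <- 0.5 / sqrt(3)
    (g(p1 * (0.5 + s) + p2 * (0.5 - s)) + g(p1 * (0.5 - s) + p2 * (0.5 + s))) / 2 *
      mesh$facet_area[facets]
  }
}

#' Solve the Darcy saddle-point system
#'
#' Schur-complement solve: the velocity mass block is factorized
#' (sparse Cholesky), and the pressure Schur complement `B' M^-1 B` is
#' inverted by conjugate gradients.  `method = "direct"` instead
#' factorizes the full indefinite saddle matrix (used as the
#' cross-check in the test-suite).
#'
#' @param sys a `darcy_system`.
#' @param method `"schur-cg"` or `"direct"`.
#' @param tol relative CG tolerance on the pressure residual.
#' @param maxit CG iteration cap.
#' @return A `flow_field` with facet-flux velocity dofs `V`, elementwise
#'   pressures `P` (Pa), and solver diagnostics.
#' @export
solve_darcy <- function(sys, method = c("schur-cg", "direct"), tol = 1e-12,
                        maxit = 10000L) {
  method <- match.arg(method)
  free <- !sys$fixed
  Mff <- sys$M[free, free, drop = FALSE]
  Bf <- sys$B[free, , drop = FALSE]
  # RHS: move fixed velocity columns; pressure row gets -B_c' V_c
  vfixv <- sys$vfix
  Ft <- sys$F[free] - as.numeric(sys$M[free, !free, drop = FALSE] %*% vfixv[!free])
  g <- -as.numeric(Matrix::crossprod(sys$B[!free, , drop = FALSE], vfixv[!free]))
  nP <- ncol(Bf)
  hist <- NULL
  if (method == "direct") {
    K <- rbind(cbind(Mff, Bf),
               cbind(Matrix::t(Bf), Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                         x = numeric(0), dims = c(nP, nP))))
    # symmetric equilibration: the velocity and divergence blocks differ
    # by many orders of magnitude in scale
    dsc <- 1 / sqrt(pmax(Matrix::rowSums(abs(K)), .Machine$double.xmin))
    Dm <- Matrix::Diagonal(x = dsc)
    sol <- dsc * as.numeric(Matrix::solve(Dm %*% K %*% Dm, dsc * c(Ft, g)))
    Vf <- sol[seq_len(nrow(Mff))]
    P <- sol[-seq_len(nrow(Mff))]
    iters <- NA_integer_
  } else {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Mff), LDL = FALSE, perm = TRUE)
    Minv <- function(x) as.numeric(Matrix::solve(ch, x, system = "A"))
    Sapply <- function(p) as.numeric(Matrix::crossprod(Bf, Minv(as.numeric(Bf %*% p))))
    rhs <- as.numeric(Matrix::crossprod(Bf, Minv(Ft))) - g
    # conjugate gradients on the SPD Schur complement
    P <- numeric(nP)
    r <- rhs
    p <- r
    rr <- sum(r * r)
    r0 <- sqrt(sum(rhs^2))
    hist <- numeric(0)
    iters <- 0L
    while (sqrt(rr) > tol * max(r0, .Machine$double.xmin) && iters < maxit) {
      Ap <- Sapply(p)
      alpha <- rr / sum(p * Ap)
      P <- P + alpha * p
      r <- r - alpha * Ap
      rr_new <- sum(r * r)
      p <- r + (rr_new / rr) * p
      rr <- rr_new
      iters <- iters + 1L
      hist <- c(hist, sqrt(rr) / r0)
    }
    if (sqrt(rr) > tol * r0)
      stop(sprintf(
        "Schur-CG stagnated after %d iterations (relative residual %.3g); see history",
        iters, sqrt(rr) / r0))
    Vf <- Minv(Ft - as.numeric(Bf %*% P))
  }
  V <- vfixv
  V[free] <- Vf
  P <- P + sys$pressure_shift
  structure(list(V = V, P = P, mesh = sys$mesh, fp = sys$fp,
                 method = method, iterations = iters, residual_history = hist),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Darcy flow field (%s, %s)\n", x$mesh$mode, x$method))
  fl <- boundary_flux(x)
  cat(sprintf("  influx (hyaloid)  %.4g m^3/s\n  outflux (retina)  %.4g m^3/s\n",
              -fl["hyaloid"], fl["retina"]))
  cat(sprintf("  pressure range    [%.6g, %.6g] Pa\n", min(x$P), max(x$P)))
  cat(sprintf("  max |div v|       %.3g 1/s\n", divergence_check(x)))
  invisible(x)
}

#' Physical volume flux through each marked boundary part
#'
#' Positive = out of the domain; units m^3/s.
#' @param flow a `flow_field`.
#' @export
boundary_flux <- function(flow) {
  mesh <- flow$mesh
  out <- c(retina = 0, lens = 0, hyaloid = 0)
  for (mk in 1:3) {
    f <- marked_facets(mesh, mk)
    if (!length(f)) next
    flx <- if (mesh$dim == 3L) flow$V[f]
    else {
      ybar <- abs(mesh$vert[mesh$facet[f, 1], 2] + mesh$vert[mesh$facet[f, 2], 2]) / 2
      pi * ybar * flow$V[f]
    }
    out[mk] <- sum(flx)
  }
  out
}

#' Maximum elementwise divergence of a solved flow
#'
#' For the mixed method this is a solver consistency check: the
#' discrete divergence (per unit cell measure) of the RT0 field must
#' vanish up to algebraic tolerance.
#' @param flow a `flow_field`.
#' @return max over cells of |div v| in 1/s.
#' @export
divergence_check <- function(flow) {
  mesh <- flow$mesh
  d <- mesh$dim
  if (d == 3L) {
    div <- rowSums(mesh$cell_facet_sign *
                     matrix(flow$V[mesh$cell_facet], nrow(mesh$cell), d + 1L)) / mesh$vol
  } else {
    ybar <- abs(mesh$vert[mesh$facet[, 1], 2] + mesh$vert[mesh$facet[, 2], 2]) / 2
    W <- matrix(pi * ybar[mesh$cell_facet], nrow(mesh$cell), d + 1L)
    div <- rowSums(mesh$cell_facet_sign * W *
                     matrix(flow$V[mesh$cell_facet], nrow(mesh$cell), d + 1L)) /
      (mesh$weights * mesh$vol)
  }
  max(abs(div))
}

# elementwise linear velocity reconstruction: v(x) on given cells/points
# v(x) = sum_l V_l sigma_l S_l / (d |K|) (x - a_l)
velocity_at <- function(flow, cells, pts) {
  mesh <- flow$mesh
  d <- mesh$dim
  out <- matrix(0, length(cells), d)
  volc <- mesh$vol[cells]
  for (l in seq_len(d + 1L)) {
    f <- mesh$cell_facet[cells, l]
    coef <- flow$V[f] * mesh$cell_facet_sign[cells, l] / (d * volc)
    out <- out + coef * (pts - mesh$vert[mesh$cell[cells, l], , drop = FALSE])
  }
  out
}

#' Summary speeds of a flow field (m/s at cell centroids)
#' @param flow a `flow_field`.
#' @export
flow_speed <- function(flow) {
  mesh <- flow$mesh
  cells <- seq_len(nrow(mesh$cell))
  cent <- 0
  for (l in seq_len(mesh$dim + 1L))
    cent <- cent + mesh$vert[mesh$cell[, l], , drop = FALSE] / (mesh$dim + 1L)
  sqrt(rowSums(velocity_at(flow, cells, cent)^2))
}
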