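#' Drug transport parameters
#'
#' @param D diffusion coefficient of the drug in the vitreous, m^2/s;
#'   either a positive scalar or (full-3d mode) a symmetric positive
#'   definite 3x3 tensor for anisotropic diffusion along collagen
#'   fibrils.  Default 4e-11 m^2/s (bevacizumab).
#' @param P retinal permeability, m/s.  The default 6e-9 m/s
#'   reproduces the clinically observed ~1-week intravitreal half-life
#'   of bevacizumab (see the methods vignette).
#' @param k dimensionless vitreous/retina partition coefficient in the
#'   retinal boundary condition.
#' @param v_settle gravitational settling speed, m/s (>= 0); see
#'   [stokes_settling_speed()].
#' @param gravity_dir unit vector of gravity in eye coordinates
#'   (x = optic axis lens -> retina); normalised with a warning if not
#'   unit length.
#' @export
transport_params <- function(D = 4e-11, P = 6e-9, k = 1, v_settle = 0,
                             gravity_dir = c(0, 0, -1)) {
  if (is.matrix(D)) {
    if (nrow(D) != 3 || ncol(D) != 3 || max(abs(D - t(D))) > 1e-12 * max(abs(D)))
      stop("tensor D must be symmetric 3x3")
    if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("tensor D must be positive definite")
  } else stopifnot(length(D) == 1, D >= 0)  # 0 only sensible in degenerate smoke tests
  stopifnot(P >= 0, k >= 0, v_settle >= 0, length(gravity_dir) == 3)
  nrm <- sqrt(sum(gravity_dir^2))
  if (abs(nrm - 1) > 1e-12) {
    warning("gravity_dir is not a unit vector; normalising")
    gravity_dir <- gravity_dir / nrm
  }
  structure(list(D = D, P = P, k = k, v_settle = v_settle,
                 gravity_dir = gravity_dir), class = "transport_params")
}

#' Stokes settling speed of a spherical particle
#'
#' `v = 2 * drho * g * a^2 / (9 * mu)`.  For a ~5 nm antibody molecule
#' this is O(1e-11) m/s, i.e. negligible against diffusion; the speed
#' is exposed as a user parameter so that stronger (e.g. aggregate or
#' emulated) settling can be studied.
#'
#' @param radius particle radius, m.
#' @param drho density excess over the suspending fluid, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param g gravitational acceleration, m/s^2.
#' @export
stokes_settling_speed <- function(radius, drho = 350, mu = 6.9e-4, g = 9.81) {
  2 * drho * g * radius^2 / (9 * mu)
}

#' Fractional-step theta time-stepping scheme
#'
#' Three sub-steps of lengths `theta*dt`, `(1-2*theta)*dt`, `theta*dt`
#' with `theta = 1 - sqrt(2)/2`, implicitness `alpha =
#' (1-2*theta)/(1-theta)` on sub-steps 1 and 3 and `1-alpha` on
#' sub-step 2.  With this classical pairing all three sub-systems share
#' one matrix `M + gamma*dt*A`, `gamma = alpha*theta`, so a single
#' factorization serves the whole macro step.  The scheme is strongly
#' A-stable and second-order accurate.
#'
#' @param dt_macro macro time step in seconds (default 0.25 days).
#' @param first_day_halved halve the macro step during the first day to
#'   resolve the bolus transient.
#' @export
theta_scheme <- function(dt_macro = 0.25 * 86400, first_day_halved = TRUE) {
  stopifnot(dt_macro > 0)
  theta <- 1 - sqrt(2) / 2
  alpha <- (1 - 2 * theta) / (1 - theta)
  structure(list(theta = theta, alpha = alpha, dt_macro = dt_macro,
                 first_day_halved = isTRUE(first_day_halved)),
            class = "theta_scheme")
}

#' Effective transport velocity (Darcy flow plus gravity settling)
#'
#' Returns an evaluator `function(cells, pts)` giving
#' `v + v_settle * gravity_dir` at points `pts` inside `cells`.
#' With `v_settle = 0` this is the Darcy field itself; `flow = NULL`
#' gives pure settling.
#'
#' @param flow a `flow_field` or `NULL`.
#' @param tp [transport_params()].
#' @param gravity_dir overrides the direction in `tp` (used by
#'   time-dependent head-orientation schedules).
#' @export
effective_velocity <- function(flow, tp, gravity_dir = tp$gravity_dir) {
  dir <- gravity_dir
  nrm <- sqrt(sum(dir^2))
  if (abs(nrm - 1) > 1e-12) {
    warning("gravity_dir is not a unit vector; normalising")
    dir <- dir / nrm
  }
  vs <- tp$v_settle
  function(cells, pts) {
    d <- ncol(pts)
    base <- if (is.null(flow)) matrix(0, length(cells), d)
    else velocity_at(flow, cells, pts)
    if (vs > 0) base + matrix(vs * dir[seq_len(d)], length(cells), d, byrow = TRUE)
    else base
  }
}


# duplicate-safe scatter-add: x[idx] += val with repeated indices
scatter_add <- function(x, idx, val) {
  rs <- rowsum(val, idx)
  j <- as.integer(rownames(rs))
  x[j] <- x[j] + rs[, 1]
  x
}

# P1 gradients per cell from the stored facet geometry:
# grad lambda_l = -(sigma_l) * n_hat(f_l) * S(f_l) / (d * |K|)
p1_gradients <- function(mesh) {
  d <- mesh$dim
  lapply(seq_len(d + 1L), function(l) {
    f <- mesh$cell_facet[, l]
    -mesh$cell_facet_sign[, l] * mesh$facet_area[f] / (d * mesh$vol) *
      mesh$facet_normal[f, , drop = FALSE]
  })
}

#' Assemble the convection-diffusion transport operators
#'
#' Weak form of `dC/dt + (v.grad)C - div(D grad C) = f` with
#' * natural zero-flux condition on the lens,
#' * Robin outflux `(P + (n.v)(k-1)) C` on the retina (the membrane
#'   permeability plus the advective partition terms),
#' * essential `C = g` on the hyaloid (default `g = 0`: the drug does
#'   not diffuse against the inflow).
#'
#' @param mesh an `eye_mesh`.
#' @param flow a solved `flow_field` on the same mesh, or `NULL` for
#'   pure diffusion.
#' @param tp [transport_params()].
#' @param gravity_dir gravity direction for the settling term.
#' @param source optional volumetric source `function(x, t)` (used by
#'   manufactured-solution verification).
#' @param dirichlet `"hyaloid"` or `"all"` (whole boundary, used by
#'   verification cases).
#' @param dirichlet_fun boundary value `function(x, t)` for the
#'   essential condition (default identically zero).
#' @param mass `"lumped"` (default; row-sum lumping, which suppresses
#'   the Galerkin ringing of the sharp initial bolus while keeping
#'   second-order accuracy) or `"consistent"`.
#' @return `transport_ops` with mass matrix `M`, combined
#'   stiffness/convection/boundary matrix `A`, Dirichlet node set, the
#'   retinal outflux functional vector and assembly metadata.
#' @export
assemble_transport <- function(mesh, flow, tp, gravity_dir = tp$gravity_dir,
                               source = NULL,
                               dirichlet = c("hyaloid", "all"),
                               dirichlet_fun = NULL,
                               mass = c("lumped", "consistent")) {
  dirichlet <- match.arg(dirichlet)
  mass <- match.arg(mass)
  stopifnot(inherits(mesh, "eye_mesh"), inherits(tp, "transport_params"))
  d <- mesh$dim
  if (d == 2L) {
    if (is.matrix(tp$D))
      stop("anisotropic diffusion requires full-3d mode")
    if (tp$v_settle > 0 && abs(abs(gravity_dir[1]) - 1) > 1e-12)
      stop("axisymmetric-2d mode supports gravity only along the optic axis; ",
           "use full-3d for lateral gravity")
  }
  nv <- nrow(mesh$vert)
  nc <- nrow(mesh$cell)
  cell <- mesh$cell
  vol <- mesh$vol
  w <- mesh$weights            # 1 (3d) or pi*|y_bar| (axisym)
  grads <- p1_gradients(mesh)
  vel <- effective_velocity(flow, tp, gravity_dir)
  rule <- if (d == 3L) quad_tet4 else quad_tri6
  qp <- simplex_quad_points(mesh$vert, cell, rule)
  qw <- lapply(seq_along(rule$w), function(q) {
    if (d == 3L) rule$w[q] * vol
    else rule$w[q] * vol * pi * abs(qp[[q]][, 2])
  })
  vq <- lapply(qp, function(x) vel(seq_len(nc), x))

  np <- (d + 1L)^2
  ii <- jj <- mm <- aa <- vector("list", np)
  n <- 0L
  for (l in seq_len(d + 1L)) for (m in seq_len(d + 1L)) {
    n <- n + 1L
    ii[[n]] <- cell[, l]; jj[[n]] <- cell[, m]
    # mass and convection by quadrature (exact for the axisym weight)
    mv <- 0; cv <- 0
    for (q in seq_along(rule$w)) {
      mv <- mv + qw[[q]] * rule$bary[q, l] * rule$bary[q, m]
      cv <- cv + qw[[q]] * rule$bary[q, l] * rowSums(vq[[q]] * grads[[m]])
    }
    # diffusion: constant gradients
    kv <- if (is.matrix(tp$D))
      rowSums((grads[[l]] %*% tp$D) * grads[[m]]) * vol * w
    else tp$D * rowSums(grads[[l]] * grads[[m]]) * vol * w
    mm[[n]] <- mv
    aa[[n]] <- kv + cv
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(mm),
                            dims = c(nv, nv))
  if (mass == "lumped")
    M <- Matrix::Diagonal(nv, as.numeric(Matrix::rowSums(M)))
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(aa),
                            dims = c(nv, nv))

  # retina Robin boundary term and the outflux functional vector
  ret <- marked_facets(mesh, 1L)
  rflux <- numeric(nv)
  if (length(ret)) {
    fv <- mesh$facet[ret, , drop = FALSE]
    nv_f <- if (d == 3L) flow_normal_speed(mesh, flow, ret) else
      flow_normal_speed(mesh, flow, ret)
    gam <- tp$P + nv_f * (tp$k - 1)        # Robin coefficient in the weak form
    gout <- tp$P + nv_f * tp$k             # physical outflux coefficient
    if (d == 3L) {
      S <- mesh$facet_area[ret]
      ii2 <- jj2 <- vv2 <- vector("list", 9L)
      n2 <- 0L
      for (l in 1:3) for (m in 1:3) {
        n2 <- n2 + 1L
        ii2[[n2]] <- fv[, l]; jj2[[n2]] <- fv[, m]
        vv2[[n2]] <- gam * S / 12 * (1 + (l == m))
      }
      R <- Matrix::sparseMatrix(i = unlist(ii2), j = unlist(jj2),
                                x = unlist(vv2), dims = c(nv, nv))
      for (l in 1:3)
        rflux <- scatter_add(rflux, fv[, l], gout * S / 3)
    } else {
      p1 <- mesh$vert[fv[, 1], , drop = FALSE]
      p2 <- mesh$vert[fv[, 2], , drop = FALSE]
      len <- mesh$facet_area[ret]
      gs <- 0.5 / sqrt(3)
      ii2 <- jj2 <- vv2 <- vector("list", 4L)
      n2 <- 0L
      for (l in 1:2) for (m in 1:2) {
        acc <- accf <- 0
        for (s in c(0.5 - gs, 0.5 + gs)) {
          x <- p1 * (1 - s) + p2 * s
          lam <- c(1 - s, s)
          acc <- acc + 0.5 * pi * abs(x[, 2]) * lam[l] * lam[m]
          if (m == 1) accf <- accf + 0.5 * pi * abs(x[, 2]) * lam[l]
        }
        n2 <- n2 + 1L
        ii2[[n2]] <- fv[, l]; jj2[[n2]] <- fv[, m]
        vv2[[n2]] <- gam * len * acc
        if (m == 1) rflux <- scatter_add(rflux, fv[, l], gout * len * accf)
      }
      R <- Matrix::sparseMatrix(i = unlist(ii2), j = unlist(jj2),
                                x = unlist(vv2), dims = c(nv, nv))
    }
    A <- A + R
  }

  dirf <- if (dirichlet == "all") mesh$boundary else marked_facets(mesh, 3L)
  dir_nodes <- sort(unique(as.vector(mesh$facet[dirf, , drop = FALSE])))
  massvec <- as.numeric(Matrix::colSums(M))   # 1'M: same for lumped/consistent

  structure(list(M = M, A = A, dir_nodes = dir_nodes,
                 dirichlet_fun = dirichlet_fun, source = source,
                 rflux = rflux, massvec = massvec,
                 mesh = mesh, flow = flow, tp = tp,
                 gravity_dir = gravity_dir,
                 cache = new.env(parent = emptyenv())),
            class = "transport_ops")
}

# outward normal speed n.v on given boundary facets (flux dof / measure)
flow_normal_speed <- function(mesh, flow, facets) {
  if (is.null(flow)) return(numeric(length(facets)))
  if (mesh$dim == 3L) flow$V[facets] / mesh$facet_area[facets]
  else flow$V[facets] / mesh$facet_area[facets]
}

# source vector int w(y) f(x,t) phi_i dx by the cell quadrature
source_vector <- function(ops, t) {
  if (is.null(ops$source)) return(numeric(nrow(ops$mesh$vert)))
  mesh <- ops$mesh
  d <- mesh$dim
  rule <- if (d == 3L) quad_tet4 else quad_tri6
  qp <- simplex_quad_points(mesh$vert, mesh$cell, rule)
  Fv <- numeric(nrow(mesh$vert))
  for (q in seq_along(rule$w)) {
    wq <- if (d == 3L) rule$w[q] * mesh$vol
    else rule$w[q] * mesh$vol * pi * abs(qp[[q]][, 2])
    fq <- ops$source(qp[[q]], t)
    for (l in seq_len(d + 1L))
      Fv <- scatter_add(Fv, mesh$cell[, l], wq * fq * rule$bary[q, l])
  }
  Fv
}

# factorized sub-step matrix M + gamma*dt*A with Dirichlet rows
substep_factor <- function(ops, gamma_dt) {
  key <- sprintf("K_%.17g", gamma_dt)
  if (!is.null(ops$cache[[key]])) return(ops$cache[[key]])
  K <- ops$M + gamma_dt * ops$A
  if (length(ops$dir_nodes)) {
    K <- Matrix::t(K)
    # zero the Dirichlet rows, then unit diagonal (column-access on dgC)
    K[, ops$dir_nodes] <- 0
    K <- Matrix::t(K)
    K <- K + Matrix::sparseMatrix(i = ops$dir_nodes, j = ops$dir_nodes,
                                  x = 1, dims = dim(K))
  }
  f <- Matrix::lu(methods::as(methods::as(K, "generalMatrix"), "CsparseMatrix"))
  ops$cache[[key]] <- f
  f
}

dirichlet_values <- function(ops, t) {
  if (is.null(ops$dirichlet_fun)) return(numeric(length(ops$dir_nodes)))
  ops$dirichlet_fun(ops$mesh$vert[ops$dir_nodes, , drop = FALSE], t)
}

#' Advance one macro step of the fractional-step theta scheme
#'
#' Three sub-steps sharing one factorized matrix; each sub-system is
#' solved by a sparse direct factorization that is cached on the
#' operator set, achieving sub-step residuals at machine precision
#' (see the methods vignette for this solver choice).
#'
#' @param C concentration nodal vector at time `t`.
#' @param ops a `transport_ops`.
#' @param scheme a [theta_scheme()].
#' @param t current time, s.
#' @param dt macro step override, s (default `scheme$dt_macro`).
#' @return nodal vector at `t + dt`.
#' @export
fractional_theta_step <- function(C, ops, scheme, t = 0, dt = scheme$dt_macro,
                                  audit = FALSE) {
  th <- scheme$theta
  al <- scheme$alpha
  be <- 1 - al
  gamma_dt <- al * th * dt               # == (1-al) * (1-2*th) * dt
  f <- substep_factor(ops, gamma_dt)
  hy_in <- 0
  ret_out <- 0
  sub <- function(C0, t0, len, a, b) {
    # (M + a*len*A) C1 = (M - b*len*A) C0 + len*(a F(t0+len) + b F(t0))
    AC0 <- as.numeric(ops$A %*% C0)
    Fab <- if (!is.null(ops$source))
      len * (a * source_vector(ops, t0 + len) + b * source_vector(ops, t0))
    else 0
    r <- as.numeric(ops$M %*% C0) - b * len * AC0 + Fab
    if (length(ops$dir_nodes))
      r[ops$dir_nodes] <- dirichlet_values(ops, t0 + len)
    C1 <- as.numeric(Matrix::solve(f, r))
    if (audit && length(ops$dir_nodes)) {
      # unconstrained residual at the Dirichlet rows = discrete mass
      # inflow through the hyaloid over this sub-step (kg)
      resid <- as.numeric(ops$M %*% (C1 - C0)) +
        len * (a * as.numeric(ops$A %*% C1) + b * AC0) - Fab
      hy_in <<- hy_in + sum(resid[ops$dir_nodes])
    }
    if (audit)   # scheme-consistent retinal outflux quadrature
      ret_out <<- ret_out + len * (a * sum(ops$rflux * C1) + b * sum(ops$rflux * C0))
    C1
  }
  C1 <- sub(C, t, th * dt, al, be)
  C2 <- sub(C1, t + th * dt, (1 - 2 * th) * dt, be, al)
  C3 <- sub(C2, t + (1 - th) * dt, th * dt, al, be)
  if (audit) {
    attr(C3, "hyaloid_in_kg") <- hy_in
    attr(C3, "retina_out_kg") <- ret_out
  }
  C3
}

#' Initial spherical drug bolus
#'
#' Nodal interpolation of a spherical indicator with a one-cell mollified
#' rim (linear ramp of width ~h/2; this bounds the Galerkin undershoot
#' of the first steps), rescaled so the discrete drug mass
#' `int_Omega C dx` equals `dose` exactly.  A ball clipped by the domain
#' boundary keeps the full dose.
#'
#' @param mesh an `eye_mesh`.
#' @param center_mm bolus centre, mm (3d coordinates; the y/z components
#'   must be 0 in axisymmetric mode unless `y` is meant as the meridian
#'   offset).
#' @param radius_mm bolus radius, mm.  Default 2.29 mm = 0.05 mL.
#' @param dose injected drug mass, kg.  Default 1.25 mg (bevacizumab).
#' @param massvec optional consistent mass functional (from
#'   `transport_ops$massvec`); computed from the mesh if missing.
#' @return nodal concentration vector, kg/m^3.
#' @export
make_initial_bolus <- function(mesh, center_mm, radius_mm = 2.29,
                               dose = 1.25e-6, massvec = NULL) {
  stopifnot(radius_mm > 0, dose > 0)
  if (!point_in_domain(mesh$domain, center_mm))
    stop(sprintf(paste0(
      "bolus centre (%.2f, %.2f, %.2f) mm lies outside the vitreous; ",
      "check the needle path (limbus distance, depth, angles)"),
      center_mm[1], center_mm[2], center_mm[3]))
  ctr <- center_mm[seq_len(mesh$dim)] * MM
  if (mesh$dim == 2L && length(center_mm) >= 3)
    ctr[2] <- sqrt(center_mm[2]^2 + center_mm[3]^2) * MM
  dist <- sqrt(rowSums((mesh$vert - matrix(ctr, nrow(mesh$vert), mesh$dim,
                                           byrow = TRUE))^2))
  ramp <- 0.5 * mesh$h_mm * MM
  C <- pmin(1, pmax(0, (radius_mm * MM - dist) / ramp + 0.5))
  if (is.null(massvec)) massvec <- p1_massvec(mesh)
  tot <- sum(massvec * C)
  if (tot <= 0) stop("bolus does not overlap the mesh")
  C * (dose / tot)
}

# consistent P1 volume functional 1'M without assembling M
p1_massvec <- function(mesh) {
  d <- mesh$dim
  rule <- if (d == 3L) quad_tet4 else quad_tri6
  qp <- simplex_quad_points(mesh$vert, mesh$cell, rule)
  out <- numeric(nrow(mesh$vert))
  for (q in seq_along(rule$w)) {
    wq <- if (d == 3L) rule$w[q] * mesh$vol
    else rule$w[q] * mesh$vol * pi * abs(qp[[q]][, 2])
    for (l in seq_len(d + 1L))
      out <- scatter_add(out, mesh$cell[, l], wq * rule$bary[q, l])
  }
  out
}

# star-shaped interior test (mm coordinates)
point_in_domain <- function(domain, x_mm, tol_mm = 0) {
  rel <- c(x_mm[1] - domain$params$mx,
           sqrt(sum(x_mm[-1]^2)))
  r <- sqrt(sum(rel^2))
  if (r == 0) return(TRUE)
  phi <- acos(pmin(1, pmax(-1, rel[1] / r)))
  r < limacon_radius(domain$params, phi) + tol_mm
}

#' Advance the drug concentration over a time horizon
#'
#' Iterates the fractional-step theta scheme to `T_s`, evaluating the
#' therapy functionals on the macro time grid.  Piecewise-constant
#' head-orientation schedules are honoured by re-assembling the
#' convection operator whenever the gravity direction switches
#' (operator factorizations are cached per orientation, so periodic
#' schedules pay the assembly cost only once per orientation).
#'
#' @param C0 initial nodal concentration (e.g. [make_initial_bolus()]).
#' @param flow solved `flow_field` (or `NULL` for pure diffusion).
#' @param tp [transport_params()].
#' @param scheme [theta_scheme()].
#' @param T_s horizon, s.
#' @param mesh mesh (defaults to the flow's).
#' @param schedule optional [head_schedule()]; default: constant
#'   `tp$gravity_dir`.
#' @param region [macula_region()] for the `J_M` observer; default ball
#'   of 2 mm at the domain's macula centre.
#' @param store_states keep all concentration snapshots (memory!).
#' @param audit accumulate the discrete boundary-flux bookkeeping.
#' @return A `transport_run`: `series` ([functional_series()]),
#'   `C_final`, `times_s`, audit record, and the peak macular amount
#'   and its time.
#' @export
advance <- function(C0, flow, tp, scheme, T_s,
                    mesh = flow$mesh, schedule = NULL,
                    region = NULL, store_states = FALSE, audit = TRUE) {
  stopifnot(T_s > 0)
  if (is.null(region))
    region <- macula_region(mesh$domain$macula_center_mm, 2)
  mvec <- region_vector(mesh, region)
  segs <- if (is.null(schedule))
    list(list(duration_s = T_s, gravity_dir = tp$gravity_dir))
  else schedule$segments
  tot <- sum(vapply(segs, function(s) s$duration_s, 0))
  if (abs(tot - T_s) > 1e-6 * T_s)
    stop(sprintf("schedule covers %.6g s but the horizon is %.6g s", tot, T_s))

  ops_cache <- list()
  get_ops <- function(gdir) {
    key <- paste(signif(gdir, 12), collapse = ",")
    if (tp$v_settle == 0) key <- "nogravity"
    if (is.null(ops_cache[[key]]))
      ops_cache[[key]] <<- assemble_transport(mesh, flow, tp, gravity_dir = gdir)
    ops_cache[[key]]
  }

  t <- 0
  C <- C0
  ops <- get_ops(segs[[1]]$gravity_dir)
  mass0 <- sum(ops$massvec * C0)
  times <- 0
  jm <- j_m(C, mvec)
  mass <- mass0
  hy_in <- 0
  ret_out_cum <- 0
  states <- if (store_states) list(C) else NULL
  day <- 86400
  iseg <- 1L
  seg_end <- segs[[1]]$duration_s
  while (t < T_s - 1e-6) {
    dt <- if (scheme$first_day_halved && t < day - 1e-6)
      scheme$dt_macro / 2 else scheme$dt_macro
    dt <- min(dt, seg_end - t, T_s - t)
    if (dt <= 1e-9) {   # advance to the next schedule segment
      iseg <- iseg + 1L
      ops <- get_ops(segs[[iseg]]$gravity_dir)
      seg_end <- seg_end + segs[[iseg]]$duration_s
      next
    }
    Cn <- fractional_theta_step(C, ops, scheme, t = t, dt = dt, audit = audit)
    if (audit) {
      hy_in <- hy_in + attr(Cn, "hyaloid_in_kg")
      ret_out_cum <- ret_out_cum + attr(Cn, "retina_out_kg")
    }
    C <- as.numeric(Cn)
    t <- t + dt
    times <- c(times, t)
    jm <- c(jm, j_m(C, mvec))
    mass <- c(mass, sum(ops$massvec * C))
    if (store_states) states[[length(states) + 1L]] <- C
  }
  series <- functional_series(times, jm, mass, mass0)
  ipk <- which.max(jm)
  structure(list(
    series = series, times_s = times, C_final = C, states = states,
    mass0 = mass0, region = region, mesh = mesh,
    peak_jm = jm[ipk], peak_time_days = times[ipk] / 86400,
    audit = if (audit) list(
      mass_initial = mass0, mass_final = mass[length(mass)],
      retina_out = ret_out_cum, hyaloid_out = -hy_in,
      imbalance = (mass0 - mass[length(mass)] - ret_out_cum + hy_in) / mass0)
    else NULL), class = "transport_run")
}

#' @export
print.transport_run <- function(x, ...) {
  s <- x$series
  n <- nrow(s)
  cat(sprintf("Transport run: %d output times over %.3g days\n", n,
              s$t_days[n]))
  cat(sprintf("  J_omega(T) = %.4f   J_M_omega(T) = %.4f   J_R(T) = %.4f\n",
              s$J_omega[n], s$J_M_omega_cum[n], s$J_R[n]))
  cat(sprintf("  peak J_M = %.4g kg at %.3g days\n", x$peak_jm,
              x$peak_time_days))
  if (!is.null(x$audit))
    cat(sprintf("  flux audit imbalance: %.3g%% of the dose\n",
                100 * abs(x$audit$imbalance)))
  invisible(x)
}
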