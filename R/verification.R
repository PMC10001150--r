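# Manufactured-solution verification of the transport discretization.
#
# Two complementary cases:
#  * spatial: a trigonometric steady concentration field with matching
#    source and Dirichlet data; the elliptic (diffusion + convection)
#    solve exposes the spatial order without time error.
#  * temporal: a field linear in space (exactly representable in P1,
#    so all spatial quadratures are exact) times a smooth decaying
#    amplitude; stepping exposes the time order of the
#    fractional-step theta scheme alone.

#' Manufactured verification case
#'
#' @param type `"space"` (trigonometric steady field) or `"time"`
#'   (linear-in-space, exponential-in-time field).
#' @param D diffusion coefficient used in the case.
#' @param v_settle,gravity_dir constant convection velocity imposed via
#'   the settling term (exercises the convection assembly without a
#'   Darcy solve).
#' @param lam decay rate of the temporal case, 1/s.
#' @return An `mms_case` bundling the exact solution, its source and
#'   the transport parameters.
#' @export
mms_case <- function(type = c("space", "time"), D = 4e-11,
                     v_settle = 2e-9, gravity_dir = c(1, 0, 0),
                     lam = 2e-6) {
  type <- match.arg(type)
  gravity_dir <- gravity_dir / sqrt(sum(gravity_dir^2))
  vvec <- v_settle * gravity_dir
  scale <- 250   # 1/m: ~2.5 periods across a 10 mm eye
  if (type == "space") {
    # even in y, so the field is a valid revolved (axisymmetric) function;
    # in 2d mode the source uses the cylindrical Laplacian
    exact <- function(x, t = 0) {
      d <- ncol(x)
      z <- if (d == 3L) x[, 3] else 0
      sin(scale * x[, 1]) * cos(0.8 * scale * x[, 2]) * cos(0.6 * scale * z)
    }
    source <- function(x, t = 0) {
      d <- ncol(x)
      z <- if (d == 3L) x[, 3] else 0
      s1 <- sin(scale * x[, 1]); c1 <- cos(scale * x[, 1])
      s2 <- sin(0.8 * scale * x[, 2]); c2 <- cos(0.8 * scale * x[, 2])
      s3 <- sin(0.6 * scale * z); c3 <- cos(0.6 * scale * z)
      lap <- -(1 + 0.64 + if (d == 3L) 0.36 else 0) * scale^2 * s1 * c2 * c3
      if (d == 2L)   # cylindrical correction (1/r) dC/dr, r = |y|
        lap <- lap - 0.8 * scale * s1 * s2 / x[, 2]
      gx <- scale * c1 * c2 * c3
      gy <- -0.8 * scale * s1 * s2 * c3
      gz <- -0.6 * scale * s1 * c2 * s3
      conv <- vvec[1] * gx + vvec[2] * gy + (if (d == 3L) vvec[3] * gz else 0)
      conv - D * lap
    }
  } else {
    # linear in space (P1-exact; in 2d only the axial coordinate is used
    # so the cylindrical Laplacian vanishes as well)
    a <- c(0.4, 120, -80, 60)    # c0 + c.x, 1/m coefficients
    g <- function(t) exp(-lam * t)
    exact <- function(x, t = 0) {
      d <- ncol(x)
      if (d == 2L) return((a[1] + a[2] * x[, 1]) * g(t))
      (a[1] + a[2] * x[, 1] + a[3] * x[, 2] + a[4] * x[, 3]) * g(t)
    }
    source <- function(x, t = 0) {
      d <- ncol(x)
      if (d == 2L) {
        lin <- a[1] + a[2] * x[, 1]
        return((-lam * lin + vvec[1] * a[2]) * g(t))
      }
      lin <- a[1] + a[2] * x[, 1] + a[3] * x[, 2] + a[4] * x[, 3]
      (-lam * lin + vvec[1] * a[2] + vvec[2] * a[3] + vvec[3] * a[4]) * g(t)
    }
  }
  structure(list(type = type, exact = exact, source = source,
                 tp = transport_params(D = D, v_settle = v_settle,
                                       gravity_dir = gravity_dir)),
            class = "mms_case")
}

# steady elliptic solve A C = F with Dirichlet rows from the case
solve_steady_transport <- function(ops, t = 0) {
  Fv <- source_vector(ops, t)
  K <- ops$A
  if (length(ops$dir_nodes)) {
    K <- Matrix::t(K)
    K[, ops$dir_nodes] <- 0
    K <- Matrix::t(K)
    K <- K + Matrix::sparseMatrix(i = ops$dir_nodes, j = ops$dir_nodes, x = 1,
                                  dims = dim(K))
    Fv[ops$dir_nodes] <- dirichlet_values(ops, t)
  }
  as.numeric(Matrix::solve(methods::as(methods::as(K, "generalMatrix"),
                                       "CsparseMatrix"), Fv))
}

# weighted L2 norm of (C_h - exact) by the cell quadrature
l2_error <- function(mesh, C, exact, t = 0) {
  d <- mesh$dim
  rule <- if (d == 3L) quad_tet4 else quad_tri6
  qp <- simplex_quad_points(mesh$vert, mesh$cell, rule)
  err2 <- 0
  nrm2 <- 0
  for (q in seq_along(rule$w)) {
    wq <- if (d == 3L) rule$w[q] * mesh$vol
    else rule$w[q] * mesh$vol * pi * abs(qp[[q]][, 2])
    ch <- 0
    for (l in seq_len(d + 1L))
      ch <- ch + rule$bary[q, l] * C[mesh$cell[, l]]
    ex <- exact(qp[[q]], t)
    err2 <- err2 + sum(wq * (ch - ex)^2)
    nrm2 <- nrm2 + sum(wq * ex^2)
  }
  sqrt(err2 / max(nrm2, .Machine$double.xmin))
}

#' Space/time convergence study on manufactured solutions
#'
#' Spatial study: solves the steady convection-diffusion problem of a
#' trigonometric manufactured field on nested meshes and reports the
#' least-squares slope of log L2-error against log h.  Temporal study:
#' advances a linear-in-space manufactured field (no spatial error)
#' with the fractional-step theta scheme over a fixed horizon at
#' halving macro steps and reports the slope against log dt.
#'
#' @param domain a `vitreous_domain` (default average eye).
#' @param mode mesh mode for the spatial study.
#' @param h_levels mesh sizes (mm) for the spatial study (>= 3).
#' @param dt_levels macro steps (s) for the temporal study (>= 3).
#' @param T_s horizon of the temporal study, s.
#' @return A `convergence_study` with error tables and observed orders;
#'   slopes are `NA` (raw tables only) if the errors are not monotone.
#' @export
convergence_study <- function(domain = build_domain(default_eye_params()),
                              mode = "axisymmetric-2d",
                              h_levels = c(1.6, 1.1, 0.8, 0.55),
                              dt_levels = 86400 / c(1, 2, 4, 8),
                              T_s = 8 * 86400) {
  stopifnot(length(h_levels) >= 3, length(dt_levels) >= 3)
  sp <- mms_case("space")
  errs_h <- vapply(h_levels, function(h) {
    mesh <- build_mesh(domain, h = h, mode = mode)
    ops <- assemble_transport(mesh, NULL, sp$tp, source = sp$source,
                              dirichlet = "all",
                              dirichlet_fun = function(x, t) sp$exact(x, t))
    C <- solve_steady_transport(ops)
    l2_error(mesh, C, sp$exact)
  }, 0)
  tm <- mms_case("time")
  mesh_t <- build_mesh(domain, h = max(h_levels), mode = mode)
  # consistent mass: linear fields are then exact in space, so the
  # study isolates the temporal error of the theta scheme
  ops_t <- assemble_transport(mesh_t, NULL, tm$tp, source = tm$source,
                              dirichlet = "all",
                              dirichlet_fun = function(x, t) tm$exact(x, t),
                              mass = "consistent")
  errs_t <- vapply(dt_levels, function(dt) {
    C <- tm$exact(mesh_t$vert, 0)
    t <- 0
    sch <- theta_scheme(dt_macro = dt, first_day_halved = FALSE)
    nstep <- round(T_s / dt)
    for (i in seq_len(nstep)) {
      C <- fractional_theta_step(C, ops_t, sch, t = t, dt = dt)
      t <- t + dt
    }
    l2_error(mesh_t, C, tm$exact, t)
  }, 0)
  slope <- function(x, err) {
    if (any(diff(err) >= 0)) return(NA_real_)   # non-monotone: no slope
    as.numeric(stats::coef(stats::lm(log(err) ~ log(x)))[2])
  }
  structure(list(
    space = data.frame(h_mm = h_levels, l2_error = errs_h),
    time = data.frame(dt_s = dt_levels, l2_error = errs_t),
    space_order = slope(h_levels, errs_h),
    time_order = slope(dt_levels, errs_t)), class = "convergence_study")
}

#' @export
print.convergence_study <- function(x, ...) {
  cat("Convergence study (manufactured solutions)\n")
  cat(sprintf("  observed spatial order:  %.3f\n", x$space_order))
  cat(sprintf("  observed temporal order: %.3f\n", x$time_order))
  print(x$space, row.names = FALSE, digits = 4)
  print(x$time, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mass-balance audit of a transport run
#'
#' Checks that the injected dose is accounted for by the remaining
#' mass, the cumulative retinal outflux (independent boundary
#' quadrature, trapezoidal in time) and the cumulative hyaloid outflux
#' (discrete Dirichlet-row bookkeeping).
#'
#' @param run a `transport_run` from [advance()] (with `audit = TRUE`).
#' @param tol acceptable relative imbalance (default 1%).
#' @return A `flux_audit` report; `ok` is `FALSE` beyond `tol`.
#' @export
flux_audit <- function(run, tol = 0.01) {
  if (is.null(run$audit))
    stop("run was advanced without audit bookkeeping")
  a <- run$audit
  out <- c(a, list(tol = tol, ok = abs(a$imbalance) <= tol))
  class(out) <- "flux_audit"
  out
}

#' @export
print.flux_audit <- function(x, ...) {
  cat("Drug mass balance over the run\n")
  cat(sprintf("  initial dose        %.6g kg\n", x$mass_initial))
  cat(sprintf("  remaining           %.6g kg (%.2f%%)\n", x$mass_final,
              100 * x$mass_final / x$mass_initial))
  cat(sprintf("  retina outflux      %.6g kg (%.2f%%)\n", x$retina_out,
              100 * x$retina_out / x$mass_initial))
  cat(sprintf("  hyaloid outflux     %.6g kg (%.2f%%)\n", x$hyaloid_out,
              100 * x$hyaloid_out / x$mass_initial))
  cat(sprintf("  imbalance           %.3g%% (tolerance %.3g%%) -> %s\n",
              100 * abs(x$imbalance), 100 * x$tol,
              if (x$ok) "PASS" else "FAIL"))
  invisible(x)
}
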