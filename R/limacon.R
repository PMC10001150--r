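#' Limacon parameter set
#'
#' Bundle the shape coefficients of the modified-Limacon vitreous profile
#' \deqn{R(q, \hat\varphi) = q_1 + q_2 \cos\hat\varphi + q_3 \cos^3\hat\varphi}
#' together with the axial centre offset `mx`.  All lengths are in
#' millimetres.  `q1` is the mean radius, `q2` and `q3` shape the
#' anterior/posterior asymmetry of the profile, and `(mx, 0)` is the
#' centre of the polar representation on the optic (x-) axis.
#'
#' @param q1,q2,q3 shape coefficients (mm); `q1 > 0`.
#' @param mx centre offset along the optic axis (mm).
#' @return An object of class `limacon_params`.
#' @examples
#' p <- limacon_params(10, 1, 0.5, mx = 0.5)
#' limacon_radius(p, 0)     # posterior pole radius q1+q2+q3
#' @export
limacon_params <- function(q1, q2 = 0, q3 = 0, mx = 0) {
  stopifnot(is.finite(q1), is.finite(q2), is.finite(q3), is.finite(mx))
  if (q1 <= 0) stop("q1 must be positive")
  p <- structure(list(q1 = q1, q2 = q2, q3 = q3, mx = mx),
                 class = "limacon_params")
  r <- limacon_radius(p, seq(0, 2 * pi, length.out = 721))
  if (any(r <= 0))
    stop("degenerate limacon: R(q, phi) must be positive on [0, 2*pi)")
  p
}

#' @export
print.limacon_params <- function(x, ...) {
  cat(sprintf(
    "Modified-Limacon vitreous profile\n  q = (%.4g, %.4g, %.4g) mm, mx = %.4g mm\n",
    x$q1, x$q2, x$q3, x$mx))
  cat(sprintf("  axial depth 2*q1 = %.4g mm, R(0) = %.4g mm, R(pi) = %.4g mm\n",
              2 * x$q1, limacon_radius(x, 0), limacon_radius(x, pi)))
  invisible(x)
}

#' Evaluate the Limacon radius
#'
#' @param params a [limacon_params()] object.
#' @param phi_hat polar angle(s) in radians, measured from the posterior
#'   (+x) pole about the centre `(mx, 0)`.
#' @return Radius `q1 + q2*cos(phi_hat) + q3*cos(phi_hat)^3` in mm.
#' @export
limacon_radius <- function(params, phi_hat) {
  cp <- cos(phi_hat)
  params$q1 + params$q2 * cp + params$q3 * cp^3
}

#' Point on the vitreous profile
#'
#' Returns the Cartesian profile point
#' `(R(q, phi) cos(phi) + mx, R(q, phi) sin(phi))` in mm.  Traversing
#' `phi` over `[0, 2*pi)` yields the closed meridian profile of the
#' vitreous body.
#'
#' @inheritParams limacon_radius
#' @param phi polar angle(s), radians.
#' @return A matrix with columns `x_mm`, `y_mm`.
#' @export
profile_point <- function(params, phi) {
  r <- limacon_radius(params, phi)
  cbind(x_mm = r * cos(phi) + params$mx, y_mm = r * sin(phi))
}

#' Ultrasound point set
#'
#' A thin validated container for extracted ultrasound profile points
#' (millimetres, meridian plane).
#'
#' @param points two-column matrix or data frame of `(x, y)` in mm.
#' @param source_label free-text provenance label.
#' @export
us_point_set <- function(points, source_label = "unlabelled") {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  colnames(points) <- c("x_mm", "y_mm")
  storage.mode(points) <- "double"
  if (nrow(points) < 8) stop("need at least 8 profile points")
  if (!all(is.finite(points))) stop("profile points must be finite")
  # collinearity guard: rank of centred coordinates must be 2
  s <- svd(scale(points, scale = FALSE))$d
  if (s[2] < 1e-9 * max(s[1], 1))
    stop("profile points are collinear; not a closed profile")
  structure(list(points = points, source_label = as.character(source_label)),
            class = "us_point_set")
}

#' @export
print.us_point_set <- function(x, ...) {
  cat(sprintf("Ultrasound point set '%s': %d points\n",
              x$source_label, nrow(x$points)))
  invisible(x)
}

#' Convert profile points to polar coordinates about (mx, 0)
#'
#' `phi_hat = arccos((x - mx)/r)` recovers only `[0, pi]`; the sign of
#' `y` restores the full angle on `[0, 2*pi)`.
#'
#' @param points a [us_point_set()] or a two-column matrix (mm).
#' @param mx centre offset (mm).
#' @return Matrix with columns `r_mm`, `phi_hat`.
#' @export
polar_convert <- function(points, mx) {
  xy <- if (inherits(points, "us_point_set")) points$points else as.matrix(points)
  dx <- xy[, 1] - mx
  y <- xy[, 2]
  r <- sqrt(dx^2 + y^2)
  if (any(r < 1e-12))
    stop("degenerate point at the polar centre (", mx, ", 0); cannot convert")
  phi <- acos(pmin(1, pmax(-1, dx / r)))
  phi <- ifelse(y < 0, 2 * pi - phi, phi)
  cbind(r_mm = r, phi_hat = phi)
}

#' Generate synthetic ultrasound profile points
#'
#' Places `n` points on the profile at equally spaced angles and
#' perturbs the radius with centred Gaussian noise, emulating the point
#' extraction from a B-scan.  Deterministic for a given `seed`.
#'
#' @inheritParams limacon_radius
#' @param n number of points (>= 8); a clinical scan yields 164.
#' @param noise_sd radial noise standard deviation, mm.
#' @param seed integer RNG seed.
#' @param source_label passed to [us_point_set()].
#' @export
generate_synthetic_us_points <- function(params, n = 164, noise_sd = 0.1,
                                         seed = 1L,
                                         source_label = "synthetic") {
  stopifnot(n >= 8, noise_sd >= 0)
  phi <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  r <- limacon_radius(params, phi)
  if (noise_sd > 0) {
    rng <- local({
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
              else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
      set.seed(as.integer(seed))
      stats::rnorm(n, 0, noise_sd)
    })
    r <- r + rng
  }
  us_point_set(cbind(r * cos(phi) + params$mx, r * sin(phi)), source_label)
}

# Residuals r_i - R(q, phi_hat_i(mx)) and the analytic Jacobian of the
# residual vector with respect to (q1, q2, q3, mx).
limacon_residuals <- function(theta, xy) {
  mx <- theta[4]
  dx <- xy[, 1] - mx
  y <- xy[, 2]
  r <- sqrt(dx^2 + y^2)
  cp <- dx / r
  res <- r - (theta[1] + theta[2] * cp + theta[3] * cp^3)
  # d cp / d mx: cp = dx/r ->  (-1/r) + dx^2/r^3 = -(y^2)/r^3
  dcp_dmx <- -(y^2) / r^3
  dr_dmx <- -dx / r
  J <- cbind(-1, -cp, -cp^3,
             dr_dmx - (theta[2] + 3 * theta[3] * cp^2) * dcp_dmx)
  list(res = res, J = J, r = r)
}

#' Fit the modified Limacon to ultrasound points
#'
#' Least-squares fit of `(q1, q2, q3, mx)` minimising
#' `sum_i (r_i - R(q, phi_hat_i(mx)))^2` with a damped Gauss-Newton
#' iteration and the analytic residual Jacobian.  The radius residual is
#' evaluated through `cos(phi_hat) = (x - mx)/r`, so the angles move
#' consistently with `mx` during the iteration.  Initialised from the
#' data centroid and mean radius unless `init` is given.
#'
#' @param points a [us_point_set()].
#' @param init optional [limacon_params()] starting value.
#' @param max_iter,tol iteration controls (relative step tolerance).
#' @return A `limacon_fit` with elements `params`, `residuals` (signed,
#'   mm), `max_abs_residual`, `rms_residual`, `converged`, `n_iter`.
#' @export
fit_limacon <- function(points, init = NULL, max_iter = 100L, tol = 1e-12) {
  stopifnot(inherits(points, "us_point_set"))
  xy <- points$points
  if (is.null(init)) {
    mx0 <- mean(xy[, 1])
    r0 <- mean(sqrt((xy[, 1] - mx0)^2 + xy[, 2]^2))
    theta <- c(r0, 0, 0, mx0)
  } else {
    stopifnot(inherits(init, "limacon_params"))
    theta <- c(init$q1, init$q2, init$q3, init$mx)
  }
  obj <- function(th) sum(limacon_residuals(th, xy)$res^2)
  lambda <- 1e-8          # Levenberg damping, raised on rejected steps
  f_old <- obj(theta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    rr <- limacon_residuals(theta, xy)
    g <- crossprod(rr$J, rr$res)
    H <- crossprod(rr$J)
    repeat {
      step <- tryCatch(
        solve(H + lambda * diag(diag(H)), -g),
        error = function(e) NULL)
      cand <- theta + as.numeric(step)
      ok <- !is.null(step) && cand[1] > 0 &&
        all(cand[1] + cand[2] * cos(seq(0, pi, length.out = 91)) +
              cand[3] * cos(seq(0, pi, length.out = 91))^3 > 0)
      f_new <- if (ok) obj(cand) else Inf
      if (f_new <= f_old) break
      lambda <- lambda * 10   # reject degenerate/uphill step, damp harder
      if (lambda > 1e12) break
    }
    if (!is.finite(f_new) || f_new > f_old) break
    rel <- sqrt(sum((cand - theta)^2)) / (1 + sqrt(sum(theta^2)))
    theta <- cand
    lambda <- max(lambda / 10, 1e-12)
    if (f_old - f_new <= tol * (1 + f_old) && rel <= sqrt(tol)) {
      converged <- TRUE
      f_old <- f_new
      break
    }
    f_old <- f_new
  }
  res <- limacon_residuals(theta, xy)$res
  structure(list(
    params = limacon_params(theta[1], theta[2], theta[3], theta[4]),
    residuals = res,
    max_abs_residual = max(abs(res)),
    rms_residual = sqrt(mean(res^2)),
    converged = converged,
    n_iter = it), class = "limacon_fit")
}

#' @export
print.limacon_fit <- function(x, ...) {
  cat(sprintf(
    "Limacon fit (%s, %d iterations)\n  max |residual| = %.4g mm, rms = %.4g mm\n",
    if (x$converged) "converged" else "NOT converged", x$n_iter,
    x$max_abs_residual, x$rms_residual))
  print(x$params)
  invisible(x)
}

#' Read / write ultrasound point CSV
#'
#' Plain CSV with header `x_mm,y_mm`; lines starting with `#` are
#' treated as comments.
#'
#' @param path file path.
#' @param source_label provenance label for the returned set.
#' @export
read_us_points <- function(path, source_label = basename(path)) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("x_mm", "y_mm") %in% names(d)))
    stop("ultrasound CSV must have columns x_mm,y_mm")
  us_point_set(cbind(d$x_mm, d$y_mm), source_label)
}

#' @rdname read_us_points
#' @param points a [us_point_set()] to write.
#' @export
write_us_points <- function(points, path) {
  stopifnot(inherits(points, "us_point_set"))
  utils::write.csv(as.data.frame(points$points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Round-trip fitted geometry as YAML
#'
#' @param params a [limacon_params()].
#' @param boundary_spec optional boundary partition (see
#'   [default_boundary_spec()]); stored alongside the shape.
#' @param path file path.
#' @export
write_geometry_yaml <- function(params, path, boundary_spec = NULL) {
  stopifnot(inherits(params, "limacon_params"))
  x <- list(limacon = list(q1 = params$q1, q2 = params$q2, q3 = params$q3,
                           mx = params$mx))
  if (!is.null(boundary_spec)) x$boundary_spec <- unclass(boundary_spec)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_geometry_yaml
#' @export
read_geometry_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  p <- x$limacon
  out <- list(params = limacon_params(p$q1, p$q2, p$q3, p$mx))
  if (!is.null(x$boundary_spec))
    out$boundary_spec <- do.call(boundary_spec, x$boundary_spec)
  out
}
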