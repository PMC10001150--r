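#' Boundary partition of the vitreous profile
#'
#' The profile circle is split into three anatomical parts by polar
#' angle `phi_hat` measured from the posterior (+x) pole:
#' * **lens** -- the anterior cap, `phi_hat > pi - lens_half`,
#' * **hyaloid** -- the inflow annulus between lens and retina,
#'   `pi - lens_half - hyaloid_width < phi_hat <= pi - lens_half`,
#' * **retina** -- everything else (the posterior shell).
#'
#' In the meridian plane (`phi` in `[0, 2*pi)`) the hyaloid therefore
#' consists of two arcs flanking the lens arc, as in the anatomy: the
#' aqueous humor enters between the lens equator and the ora serrata.
#' Angles are half-openings in degrees.
#'
#' @param lens_half half-opening of the anterior lens cap (deg).
#' @param hyaloid_width angular width of the hyaloid inflow band (deg).
#' @return A `boundary_spec` object.
#' @export
boundary_spec <- function(lens_half = 30, hyaloid_width = 10) {
  stopifnot(lens_half >= 0, hyaloid_width >= 0, lens_half + hyaloid_width < 180)
  structure(list(lens_half = lens_half, hyaloid_width = hyaloid_width),
            class = "boundary_spec")
}

#' @rdname boundary_spec
#' @export
default_boundary_spec <- function() boundary_spec()

# Marker id for polar angle phi_hat (radians from +x pole).
# 1 = retina, 2 = lens, 3 = hyaloid (matching the VTU boundary_id field).
marker_for_angle <- function(phi_hat, spec) {
  a <- acos(pmin(1, pmax(-1, cos(phi_hat))))   # fold to [0, pi]
  lens_lo <- pi - spec$lens_half * pi / 180
  hy_lo <- lens_lo - spec$hyaloid_width * pi / 180
  ifelse(a > lens_lo, 2L, ifelse(a > hy_lo, 3L, 1L))
}

#' Build the vitreous computational domain
#'
#' Combines a fitted Limacon profile with a boundary partition and
#' places the macula centre on the retinal boundary at the posterior
#' pole (optic axis), optionally offset along the profile to
#' distinguish macula from optic-nerve head.
#'
#' @param params a [limacon_params()] (mm).
#' @param spec a [boundary_spec()].
#' @param macula_offset_deg angular offset of the macula centre from the
#'   posterior pole, degrees along the meridian (0 = on the optic axis).
#' @return A `vitreous_domain` with the profile, the partition, the
#'   macula centre (mm, on the boundary) and the optic axis (+x, lens to
#'   retina).
#' @export
build_domain <- function(params, spec = default_boundary_spec(),
                         macula_offset_deg = 0) {
  stopifnot(inherits(params, "limacon_params"), inherits(spec, "boundary_spec"))
  phi_m <- macula_offset_deg * pi / 180
  if (marker_for_angle(phi_m, spec) != 1L)
    stop("macula centre must lie on the retina arc")
  m <- profile_point(params, phi_m)[1, ]
  structure(list(
    params = params,
    spec = spec,
    macula_center_mm = c(m[["x_mm"]], m[["y_mm"]], 0),
    optic_axis = c(1, 0, 0)), class = "vitreous_domain")
}

#' @export
print.vitreous_domain <- function(x, ...) {
  cat("Vitreous domain\n")
  print(x$params)
  cat(sprintf("  lens cap %g deg, hyaloid band %g deg, macula at (%.3g, %.3g, %.3g) mm\n",
              x$spec$lens_half, x$spec$hyaloid_width,
              x$macula_center_mm[1], x$macula_center_mm[2], x$macula_center_mm[3]))
  invisible(x)
}

#' Angular measures of the three boundary arcs in the meridian plane
#'
#' @param domain a `vitreous_domain`.
#' @return Named vector of arc angular measures (radians) over the full
#'   profile circle `[0, 2*pi)`.
#' @export
arc_measures <- function(domain) {
  spec <- domain$spec
  lens <- 2 * spec$lens_half * pi / 180
  hyaloid <- 2 * spec$hyaloid_width * pi / 180
  c(retina = 2 * pi - lens - hyaloid, lens = lens, hyaloid = hyaloid)
}

#' Default average Virtual-Eye shape
#'
#' A Limacon whose axial depth and equatorial width (both `2*q1`) sit
#' between the anatomical vitreous depth (~17 mm) and width (~21 mm),
#' with a mild anterior flattening; vitreous volume ~4.2 mL.
#'
#' @export
default_eye_params <- function() limacon_params(10, 1, 0.5, mx = 0.5)
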