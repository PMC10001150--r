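# Mesh construction for the vitreous domain.
#
# full-3d:          the cube lattice [-1,1]^3 is subdivided into
#                   Freudenthal tetrahedra (6 per cell, conforming) and
#                   mapped radially onto the star-shaped revolved
#                   Limacon: x = c + rho * R(phi_hat) * u_hat, where rho
#                   is the sup-norm of the lattice point and u_hat its
#                   direction.  Boundary vertices land exactly on the
#                   profile surface.
# axisymmetric-2d:  polar triangle mesh of the full meridian profile
#                   region; cylindrical integrals use the weight
#                   pi * |y| so that the doubled (y<0) half counts once.
#
# Vertices are stored in metres; the geometry API is in millimetres.

MM <- 1e-3   # mm -> m

freudenthal_tets <- function(n) {
  # lattice (2n+1)^3 over [-1,1]^3, 6 tets per cube, consistent diagonals
  m <- 2L * n + 1L
  vid <- function(i, j, k) (k - 1L) * m * m + (j - 1L) * m + i
  g <- as.matrix(expand.grid(i = 1:(m - 1L), j = 1:(m - 1L), k = 1:(m - 1L)))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- vector("list", 6L)
  for (p in 1:6) {
    e <- diag(3L)[perms[p, ], , drop = FALSE]
    v0 <- g
    v1 <- v0 + e[rep(1L, nrow(g)), ]
    v2 <- v1 + e[rep(2L, nrow(g)), ]
    v3 <- v2 + e[rep(3L, nrow(g)), ]
    cells[[p]] <- cbind(vid(v0[, 1], v0[, 2], v0[, 3]),
                        vid(v1[, 1], v1[, 2], v1[, 3]),
                        vid(v2[, 1], v2[, 2], v2[, 3]),
                        vid(v3[, 1], v3[, 2], v3[, 3]))
  }
  xs <- seq(-1, 1, length.out = m)
  verts <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  list(verts = verts, cells = do.call(rbind, cells))
}

star_map <- function(p, params) {
  # lattice point in [-1,1]^3 -> point of the revolved Limacon (mm).
  # Smooth cube-to-ball map (no diagonal kinks, hence no sliver cells):
  # each coordinate x' = x * sqrt(1 - y^2/2 - z^2/2 + y^2 z^2 / 3) maps
  # the cube surface exactly onto the unit sphere; the result is then
  # scaled radially by the Limacon radius of its polar angle.
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  u <- cbind(x * sqrt(pmax(0, 1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3)),
             y * sqrt(pmax(0, 1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3)),
             z * sqrt(pmax(0, 1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3)))
  n2 <- sqrt(rowSums(u^2))
  dirx <- ifelse(n2 > 0, u[, 1] / pmax(n2, 1e-300), 1)
  phi_hat <- acos(pmin(1, pmax(-1, dirx)))
  r <- limacon_radius(params, phi_hat)
  cbind(params$mx + r * u[, 1], r * u[, 2], r * u[, 3])
}

tet_volumes <- function(vert, cell) {
  a <- vert[cell[, 1], , drop = FALSE]
  b <- vert[cell[, 2], , drop = FALSE] - a
  c3 <- vert[cell[, 3], , drop = FALSE] - a
  d <- vert[cell[, 4], , drop = FALSE] - a
  (b[, 1] * (c3[, 2] * d[, 3] - c3[, 3] * d[, 2]) -
     b[, 2] * (c3[, 1] * d[, 3] - c3[, 3] * d[, 1]) +
     b[, 3] * (c3[, 1] * d[, 2] - c3[, 2] * d[, 1])) / 6
}

tri_areas2d <- function(vert, cell) {
  a <- vert[cell[, 1], , drop = FALSE]
  b <- vert[cell[, 2], , drop = FALSE] - a
  c2 <- vert[cell[, 3], , drop = FALSE] - a
  (b[, 1] * c2[, 2] - b[, 2] * c2[, 1]) / 2
}

# unique facets of a simplex mesh; returns facet table, facet->cell map,
# and per-cell facet ids/signs (facet l is opposite local vertex l)
build_facets <- function(cell, nv, d) {
  nc <- nrow(cell)
  loc <- utils::combn(d + 1L, d)          # facet l uses columns != l
  # order local facets so that facet l is opposite vertex l
  opp <- apply(loc, 2, function(co) setdiff(seq_len(d + 1L), co))
  ord <- order(opp)
  loc <- loc[, ord, drop = FALSE]
  fac_all <- do.call(rbind, lapply(seq_len(d + 1L), function(l)
    cell[, loc[, l], drop = FALSE]))
  fac_sorted <- if (d == 3L) {
    lo <- pmin(fac_all[, 1], fac_all[, 2], fac_all[, 3])
    hi <- pmax(fac_all[, 1], fac_all[, 2], fac_all[, 3])
    cbind(lo, fac_all[, 1] + fac_all[, 2] + fac_all[, 3] - lo - hi, hi)
  } else {
    cbind(pmin(fac_all[, 1], fac_all[, 2]), pmax(fac_all[, 1], fac_all[, 2]))
  }
  key <- if (d == 3L)
    (fac_sorted[, 1] - 1) * nv * nv + (fac_sorted[, 2] - 1) * nv + fac_sorted[, 3]
  else (fac_sorted[, 1] - 1) * nv + fac_sorted[, 2]
  uk <- !duplicated(key)
  fid <- match(key, key[uk])
  facet <- fac_sorted[uk, , drop = FALSE]
  nf <- nrow(facet)
  cell_facet <- matrix(fid, nrow = nc, ncol = d + 1L)
  # facet -> adjacent cells (1 or 2)
  cid <- rep(seq_len(nc), d + 1L)
  o <- order(fid)
  f_sorted <- fid[o]; c_sorted <- cid[o]
  first <- !duplicated(f_sorted)
  facet_cell <- matrix(0L, nf, 2L)
  facet_cell[f_sorted[first], 1L] <- c_sorted[first]
  facet_cell[f_sorted[!first], 2L] <- c_sorted[!first]
  list(facet = facet, facet_cell = facet_cell, cell_facet = cell_facet)
}

#' Build a conforming mesh of the vitreous domain
#'
#' @param domain a [build_domain()] result.
#' @param h target edge length, mm.
#' @param mode `"full-3d"` (Freudenthal tetrahedra of the revolved
#'   solid) or `"axisymmetric-2d"` (polar triangles of the meridian
#'   profile region).
#' @param rho_min axisymmetric mode only: inner relative radius of an
#'   annular (spherical-shell) domain.  The default 0 meshes the full
#'   profile region; a positive value is used by verification
#'   benchmarks with analytic radial solutions, and the inner boundary
#'   is marked as inflow (marker 3).
#' @return An `eye_mesh` with vertices in metres, positively oriented
#'   cells, unique facets, outward facet normals and boundary markers
#'   (1 = retina, 2 = lens, 3 = hyaloid, as in the exported
#'   `boundary_id` field).
#' @export
build_mesh <- function(domain, h = 1, mode = c("full-3d", "axisymmetric-2d"),
                       rho_min = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(domain, "vitreous_domain"), h > 0,
            rho_min >= 0, rho_min < 1)
  params <- domain$params
  rmax <- max(limacon_radius(params, seq(0, pi, length.out = 361)))
  if (mode == "full-3d") {
    n <- max(2L, as.integer(round(rmax / h)))
    fr <- freudenthal_tets(n)
    vert <- star_map(fr$verts, params) * MM
    cell <- fr$cells
    vol <- tet_volumes(vert, cell)
    flip <- vol < 0
    if (any(flip)) cell[flip, 3:4] <- cell[flip, c(4, 3)]
    vol <- abs(vol)
    if (any(vol <= 0)) stop("mesher failure: degenerate tetrahedron")
    fb <- build_facets(cell, nrow(vert), 3L)
    # facet geometry
    p1 <- vert[fb$facet[, 1], ]; p2 <- vert[fb$facet[, 2], ]; p3 <- vert[fb$facet[, 3], ]
    cr <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
                (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
                (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
    area <- 0.5 * sqrt(rowSums(cr^2))
    normal <- cr / (2 * area)
    fcent <- (p1 + p2 + p3) / 3
    ccent <- (vert[cell[, 1], ] + vert[cell[, 2], ] + vert[cell[, 3], ] + vert[cell[, 4], ]) / 4
    outw <- rowSums(normal * (fcent - ccent[fb$facet_cell[, 1], ])) > 0
    normal[!outw, ] <- -normal[!outw, , drop = FALSE]
    d <- 3L
  } else {
    nphi <- max(8L, as.integer(round(pi * rmax / h)))
    nr <- max(2L, as.integer(round(rmax / h)))
    ang <- seq(0, 2 * pi, length.out = 2L * nphi + 1L)[seq_len(2L * nphi)]
    na <- length(ang)
    annulus <- rho_min > 0
    off <- if (annulus) 0L else 1L           # centre vertex present?
    ring_id <- function(j, i) off + (j - 1L) * na + ((i - 1L) %% na) + 1L
    verts_mm <- if (annulus) matrix(0, 0, 2) else rbind(c(params$mx, 0))
    j0 <- if (annulus) 0L else 1L
    for (j in j0:nr) {
      rho <- rho_min + (1 - rho_min) * j / nr
      r <- rho * limacon_radius(params, ang)
      verts_mm <- rbind(verts_mm, cbind(params$mx + r * cos(ang), r * sin(ang)))
    }
    if (annulus) ring_id <- function(j, i) (j) * na + ((i - 1L) %% na) + 1L
    cells <- matrix(0L, 0L, 3L)
    if (!annulus) for (i in seq_len(na))   # centre fan
      cells <- rbind(cells, c(1L, ring_id(1L, i), ring_id(1L, i + 1L)))
    jseq <- if (annulus) 0:(nr - 1L) else seq_len(nr - 1L)
    for (j in jseq) {
      a <- ring_id(j, seq_len(na));      b <- ring_id(j, seq_len(na) + 1L)
      c2 <- ring_id(j + 1L, seq_len(na)); d2 <- ring_id(j + 1L, seq_len(na) + 1L)
      cells <- rbind(cells, cbind(a, c2, d2), cbind(a, d2, b))
    }
    vert <- verts_mm * MM
    cell <- cells
    vol <- tri_areas2d(vert, cell)
    flip <- vol < 0
    if (any(flip)) cell[flip, 2:3] <- cell[flip, c(3, 2)]
    vol <- abs(vol)
    if (any(vol <= 0)) stop("mesher failure: degenerate triangle")
    fb <- build_facets(cell, nrow(vert), 2L)
    p1 <- vert[fb$facet[, 1], ]; p2 <- vert[fb$facet[, 2], ]
    ev <- p2 - p1
    area <- sqrt(rowSums(ev^2))
    normal <- cbind(ev[, 2], -ev[, 1]) / area
    fcent <- (p1 + p2) / 2
    ccent <- (vert[cell[, 1], ] + vert[cell[, 2], ] + vert[cell[, 3], ]) / 3
    outw <- rowSums(normal * (fcent - ccent[fb$facet_cell[, 1], ])) > 0
    normal[!outw, ] <- -normal[!outw, , drop = FALSE]
    d <- 2L
  }
  nb <- fb$facet_cell[, 2] == 0L
  marker <- rep(NA_integer_, nrow(fb$facet))
  centre <- c(params$mx, 0, 0)[seq_len(d)] * MM
  rel <- fcent[nb, , drop = FALSE] - matrix(centre, sum(nb), d, byrow = TRUE)
  phi_hat <- acos(pmin(1, pmax(-1, rel[, 1] / sqrt(rowSums(rel^2)))))
  marker[nb] <- marker_for_angle(phi_hat, domain$spec)
  if (mode == "axisymmetric-2d" && rho_min > 0) {
    rrel <- sqrt(rowSums(rel^2)) / (limacon_radius(params, phi_hat) * MM)
    marker[nb][rrel < rho_min + 0.5 * (1 - rho_min) / nr] <- 3L
  }
  # per-cell facet orientation signs (+1 if stored normal is outward)
  sgn <- matrix(1, nrow(cell), d + 1L)
  for (l in seq_len(d + 1L)) {
    f <- fb$cell_facet[, l]
    sgn[, l] <- ifelse(fb$facet_cell[f, 1L] == seq_len(nrow(cell)), 1, -1)
  }
  m <- structure(list(
    mode = mode, dim = d, h_mm = h, domain = domain,
    vert = vert, cell = cell, vol = vol,
    facet = fb$facet, facet_cell = fb$facet_cell,
    cell_facet = fb$cell_facet, cell_facet_sign = sgn,
    facet_area = area, facet_normal = normal, facet_center = fcent,
    boundary = which(nb), marker = marker), class = "eye_mesh")
  m$weights <- cell_weights(m)
  m
}

# cylindrical measure weight per cell: 1 for 3d, pi*|y_bar| for axisym
# (the meridian mesh covers both half-planes, so each counts half)
cell_weights <- function(mesh) {
  if (mesh$mode == "full-3d") rep(1, nrow(mesh$cell))
  else {
    yb <- (abs(mesh$vert[mesh$cell[, 1], 2]) + abs(mesh$vert[mesh$cell[, 2], 2]) +
             abs(mesh$vert[mesh$cell[, 3], 2])) / 3
    pi * yb
  }
}

#' Mesh measure (volume of the represented 3d domain)
#'
#' For `full-3d`, the sum of tetrahedron volumes; for
#' `axisymmetric-2d`, the revolved volume `int pi |y| dA` over the full
#' meridian mesh.  In cubic metres.
#' @param mesh an `eye_mesh`.
#' @export
mesh_volume <- function(mesh) sum(mesh$weights * mesh$vol)

#' Meridian-plane area of an axisymmetric mesh (m^2)
#' @param mesh an `eye_mesh` in axisymmetric-2d mode.
#' @export
mesh_area <- function(mesh) {
  stopifnot(mesh$mode == "axisymmetric-2d")
  sum(mesh$vol)
}

#' @export
print.eye_mesh <- function(x, ...) {
  cat(sprintf("eye_mesh (%s): %d vertices, %d cells, %d facets (%d boundary)\n",
              x$mode, nrow(x$vert), nrow(x$cell), nrow(x$facet),
              length(x$boundary)))
  tab <- table(factor(x$marker[x$boundary], levels = 1:3,
                      labels = c("retina", "lens", "hyaloid")))
  cat("  boundary facets:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  cat(sprintf("  volume %.4g mm^3\n", mesh_volume(x) / MM^3))
  invisible(x)
}

# boundary facet ids with a given marker (1 retina, 2 lens, 3 hyaloid)
marked_facets <- function(mesh, marker) {
  mesh$boundary[mesh$marker[mesh$boundary] == marker]
}
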