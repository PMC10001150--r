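#' Macular region of interest
#'
#' The site of drug action is modelled as the ball `B_r(m)` intersected
#' with the vitreous, with `m` on the retina at the posterior pole and
#' `r = 2` mm by convention.
#'
#' @param center_mm macula centre, mm (length 3).
#' @param radius_mm ball radius, mm (> 0).
#' @export
macula_region <- function(center_mm, radius_mm = 2) {
  stopifnot(radius_mm > 0, length(center_mm) == 3)
  structure(list(center_mm = center_mm, radius_mm = radius_mm),
            class = "macula_region")
}

# midpoint-subdivision tables: child vertices in parent barycentric coords
subdiv_children <- function(d) {
  if (d == 3L) {
    v <- list(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0), c = c(0, 0, 1, 0),
              e = c(0, 0, 0, 1))
    m <- function(p, q) (v[[p]] + v[[q]]) / 2
    ch <- list(
      rbind(v$a, m("a", "b"), m("a", "c"), m("a", "e")),
      rbind(m("a", "b"), v$b, m("b", "c"), m("b", "e")),
      rbind(m("a", "c"), m("b", "c"), v$c, m("c", "e")),
      rbind(m("a", "e"), m("b", "e"), m("c", "e"), v$e),
      # central octahedron split along the (ac)-(be) diagonal
      rbind(m("a", "b"), m("a", "c"), m("a", "e"), m("b", "e")),
      rbind(m("a", "b"), m("b", "c"), m("b", "e"), m("a", "c")),
      rbind(m("a", "c"), m("b", "c"), m("c", "e"), m("b", "e")),
      rbind(m("a", "c"), m("c", "e"), m("a", "e"), m("b", "e")))
  } else {
    v <- list(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
    m <- function(p, q) (v[[p]] + v[[q]]) / 2
    ch <- list(rbind(v$a, m("a", "b"), m("a", "c")),
               rbind(m("a", "b"), v$b, m("b", "c")),
               rbind(m("a", "c"), m("b", "c"), v$c),
               rbind(m("a", "b"), m("b", "c"), m("a", "c")))
  }
  ch
}

#' Quadrature functional vector of a region
#'
#' Builds the sparse nodal functional `m` with
#' `m' C = int_{B_r(m) cap Omega} C dx` by quadrature-point membership.
#' Cells cut by the sphere get one level of midpoint subdivision to
#' bound the geometric bias; a quadrature point exactly on the sphere
#' counts as inside.
#'
#' @param mesh an `eye_mesh`.
#' @param region a [macula_region()].
#' @return numeric vector over mesh vertices.
#' @export
region_vector <- function(mesh, region) {
  d <- mesh$dim
  ctr <- region$center_mm[seq_len(d)] * MM
  if (d == 2L) {
    if (abs(region$center_mm[2]) + abs(region$center_mm[3]) > 1e-12)
      stop("axisymmetric mode requires the region centre on the optic axis")
    ctr <- c(region$center_mm[1] * MM, 0)
  }
  r2 <- (region$radius_mm * MM)^2
  vd <- sqrt(rowSums((mesh$vert - matrix(ctr, nrow(mesh$vert), d,
                                         byrow = TRUE))^2))
  vin <- matrix(vd[mesh$cell] <= region$radius_mm * MM, nrow(mesh$cell))
  nin <- rowSums(vin)
  hmax <- mesh$h_mm * MM * 2
  cut <- nin > 0 & nin < (d + 1L) |
    (nin == 0 & apply(matrix(vd[mesh$cell], nrow(mesh$cell)), 1, min) <
       region$radius_mm * MM + hmax)
  rule <- if (d == 3L) quad_tet4 else quad_tri6
  out <- numeric(nrow(mesh$vert))
  add_cells <- function(cells, bary_tab, volfrac) {
    # bary_tab: child-vertex coords in parent barycentric (identity for
    # unsubdivided cells)
    cellm <- mesh$cell[cells, , drop = FALSE]
    volc <- mesh$vol[cells] * volfrac
    for (q in seq_along(rule$w)) {
      pb <- as.numeric(rule$bary[q, ] %*% bary_tab)   # parent barycentric
      x <- 0
      for (l in seq_len(d + 1L))
        x <- x + pb[l] * mesh$vert[cellm[, l], , drop = FALSE]
      inside <- rowSums((x - matrix(ctr, length(cells), d, byrow = TRUE))^2) <= r2
      if (!any(inside)) next
      wq <- rule$w[q] * volc * (if (d == 3L) 1 else pi * abs(x[, 2]))
      wq <- wq * inside
      for (l in seq_len(d + 1L))
        out <<- scatter_add(out, cellm[, l], wq * pb[l])
    }
  }
  plain <- which(!cut)
  if (length(plain))
    add_cells(plain, diag(d + 1L), 1)
  if (any(cut)) {
    ch <- subdiv_children(d)
    for (tab in ch)
      add_cells(which(cut), tab, 1 / length(ch))
  }
  out
}

#' Fraction of drug remaining in the vitreous
#'
#' `J_Omega(t) = int C(t) dx / int C(0) dx` with the consistent mass
#' quadrature.
#'
#' @param C nodal concentration at time t.
#' @param C0 nodal concentration at time 0 (or `mass0` directly).
#' @param massvec consistent volume functional (`transport_ops$massvec`
#'   or [p1_massvec()] of the mesh).
#' @param mass0 initial mass, kg (alternative to `C0`).
#' @export
j_omega <- function(C, C0 = NULL, massvec, mass0 = NULL) {
  if (is.null(mass0)) mass0 <- sum(massvec * C0)
  if (!is.finite(mass0) || mass0 <= 0) stop("initial drug mass must be positive")
  sum(massvec * C) / mass0
}

#' Drug amount in the macular region
#'
#' `J_M(t) = int_{B_r(m) cap Omega} C(t) dx` in kg.
#'
#' @param C nodal concentration.
#' @param mvec region functional from [region_vector()] (pass the
#'   vector to avoid rebuilding it every time step).
#' @export
j_m <- function(C, mvec) {
  if (all(mvec == 0)) stop("macular region does not intersect the domain")
  sum(mvec * C)
}

#' Time-integrated macular exposure
#'
#' Trapezoidal integral of `J_M(t) / int C(0) dx` over `[0, T]`, with
#' time measured in days: the average daily macular fraction of the
#' injected dose accumulated over the horizon.  By construction it
#' overestimates the drug that can react at the macula, since residence
#' is counted repeatedly.
#'
#' @param times_s output time grid, s (nondecreasing, from 0).
#' @param jm `J_M` series on that grid, kg.
#' @param mass0 injected mass, kg.
#' @param T_s optional upper limit (defaults to the last time).
#' @export
j_m_omega <- function(times_s, jm, mass0, T_s = times_s[length(times_s)]) {
  stopifnot(length(times_s) == length(jm), mass0 > 0)
  if (is.unsorted(times_s)) stop("time grid must be nondecreasing")
  keep <- times_s <= T_s + 1e-9
  t_d <- times_s[keep] / 86400
  y <- jm[keep] / mass0
  sum(diff(t_d) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Retinal loss fraction
#'
#' Conservation form `J_R(T) = 1 - J_Omega(T) - J_M_Omega(T)`: the share
#' of the injected drug neither remaining in the vitreous nor counted
#' as macular exposure.  Values outside `[-eps, 1+eps]` are flagged.
#'
#' @param j_omega_T,j_m_omega_T the other functionals at the horizon.
#' @param eps consistency slack.
#' @export
j_r <- function(j_omega_T, j_m_omega_T, eps = 1e-6) {
  out <- 1 - j_omega_T - j_m_omega_T
  if (out < -eps || out > 1 + eps)
    warning(sprintf("J_R = %.4g outside [0, 1]: inconsistent functional inputs",
                    out))
  out
}

#' Assemble the therapy-functional time series
#'
#' @param times_s output times, s.
#' @param jm `J_M` series, kg.
#' @param mass drug-mass series, kg.
#' @param mass0 initial mass, kg.
#' @return A `functional_series` data frame with columns `t_days`,
#'   `J_omega`, `J_M`, `J_M_omega_cum`, `J_R`.
#' @export
functional_series <- function(times_s, jm, mass, mass0 = mass[1]) {
  n <- length(times_s)
  stopifnot(length(jm) == n, length(mass) == n)
  t_d <- times_s / 86400
  jom <- mass / mass0
  y <- jm / mass0
  jmo <- c(0, cumsum(diff(t_d) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  out <- data.frame(t_days = t_d, J_omega = jom, J_M = jm,
                    J_M_omega_cum = jmo, J_R = 1 - jom - jmo)
  class(out) <- c("functional_series", "data.frame")
  out
}
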