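#' Intravitreal injection specification
#'
#' The needle enters the globe on the meridian plane `z = 0` at `y > 0`
#' (injection from the left into the left eye), at an arc distance
#' `limbus_distance` posterior to the limbus ring, and advances
#' `needle_depth` along the direction given by the two penetration
#' angles: `psi_xy` between the needle and the optic (x-) axis within
#' the xy-plane, and `psi_z` against the z-axis (`90` = needle in the
#' xy-plane).  The bolus is released at the needle tip.
#'
#' @param limbus_distance_mm arc distance from the limbus along the
#'   globe surface, mm.
#' @param needle_depth_mm insertion depth from the entry point, mm.
#' @param psi_xy_deg,psi_z_deg penetration angles, degrees, in (0, 180).
#' @param bolus_radius_mm radius of the injected spherical bolus
#'   (default 2.29 mm = 0.05 mL).
#' @param dose_kg injected drug mass (default 1.25 mg, the bevacizumab
#'   convention; all therapy functionals are dose-invariant).
#' @export
injection_spec <- function(limbus_distance_mm = 3.5, needle_depth_mm = 5,
                           psi_xy_deg = 50, psi_z_deg = 90,
                           bolus_radius_mm = 2.29, dose_kg = 1.25e-6) {
  stopifnot(needle_depth_mm >= 0, limbus_distance_mm >= 0,
            psi_xy_deg > 0, psi_xy_deg < 180,
            psi_z_deg > 0, psi_z_deg < 180,
            bolus_radius_mm > 0, dose_kg > 0)
  structure(list(limbus_distance_mm = limbus_distance_mm,
                 needle_depth_mm = needle_depth_mm,
                 psi_xy_deg = psi_xy_deg, psi_z_deg = psi_z_deg,
                 bolus_radius_mm = bolus_radius_mm, dose_kg = dose_kg),
            class = "injection_spec")
}

#' The four injection-position presets
#'
#' Standard (pars plana, toward the posterior pole), central vitreous,
#' lateral near the optic nerve, and deep insertion close to the
#' macula.  Limbus distances follow the clinical description; needle
#' depths are adapted so the tip stays interior to the default
#' geometry.
#' @export
injection_positions <- function() {
  list(standard = injection_spec(3.5, 5, 50, 90),
       center = injection_spec(10, 10, 90, 90),
       nerve = injection_spec(8, 7.5, 65, 90),
       macula = injection_spec(10, 14.5, 40, 90))
}

#' Needle entry point on the globe
#'
#' The limbus ring is identified with the lens-arc / hyaloid junction
#' of the profile; the entry point lies `limbus_distance` further
#' posterior, measured as arc length along the meridian profile.
#'
#' @param inj an [injection_spec()].
#' @param domain a `vitreous_domain`.
#' @return entry point, mm, in the `z = 0`, `y > 0` meridian.
#' @export
needle_entry_point <- function(inj, domain) {
  phi_limbus <- pi - domain$spec$lens_half * pi / 180
  # cumulative arc length from the limbus toward the posterior pole
  ph <- seq(phi_limbus, 0, length.out = 4001)
  p <- profile_point(domain$params, ph)
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  if (inj$limbus_distance_mm > max(s))
    stop("limbus distance exceeds the profile arc length")
  i <- which.min(abs(s - inj$limbus_distance_mm))
  c(p[i, 1], p[i, 2], 0)
}

#' Needle tip position
#'
#' `tip = entry + depth * d(psi_xy, psi_z)` with
#' `d = (sin(psi_z) cos(psi_xy), -sin(psi_z) sin(psi_xy), cos(psi_z))`;
#' the tip must lie strictly inside the vitreous.
#'
#' @inheritParams needle_entry_point
#' @return tip position, mm.
#' @export
needle_tip_position <- function(inj, domain) {
  entry <- needle_entry_point(inj, domain)
  pxy <- inj$psi_xy_deg * pi / 180
  pz <- inj$psi_z_deg * pi / 180
  dir <- c(sin(pz) * cos(pxy), -sin(pz) * sin(pxy), cos(pz))
  tip <- entry + inj$needle_depth_mm * dir
  if (!point_in_domain(domain, tip, tol_mm = 1e-6)) {
    rel <- c(tip[1] - domain$params$mx, sqrt(tip[2]^2 + tip[3]^2))
    r <- sqrt(sum(rel^2))
    Rb <- limacon_radius(domain$params,
                         acos(pmin(1, pmax(-1, rel[1] / max(r, 1e-12)))))
    stop(sprintf(
      "needle tip (%.2f, %.2f, %.2f) mm lies outside the vitreous (%.2f mm beyond the boundary)",
      tip[1], tip[2], tip[3], r - Rb))
  }
  tip
}

#' Gravity direction for a head orientation
#'
#' Left-eye convention with the optic axis x pointing lens -> retina:
#' standing `(0,0,-1)`; lying on the back `(1,0,0)` (gravity toward the
#' posterior pole); lying on the left side `(0,-1,0)`; on the right
#' side `(0,1,0)`.
#'
#' @param orientation one of `"standing"`, `"back"`, `"left"`,
#'   `"right"`.
#' @export
head_orientation_to_gravity <- function(orientation) {
  switch(orientation,
         standing = c(0, 0, -1),
         back = c(1, 0, 0),
         left = c(0, -1, 0),
         right = c(0, 1, 0),
         stop("unknown head orientation '", orientation,
              "' (use standing/back/left/right)"))
}

#' Head-orientation schedule
#'
#' An ordered sequence of `(duration, orientation)` segments covering
#' the simulation horizon.
#'
#' @param orientations character vector of orientations (or a list of
#'   gravity unit vectors).
#' @param durations_s segment durations, s (positive).
#' @export
head_schedule <- function(orientations, durations_s) {
  stopifnot(length(orientations) == length(durations_s),
            all(durations_s > 0))
  segs <- lapply(seq_along(durations_s), function(i) {
    g <- if (is.character(orientations))
      head_orientation_to_gravity(orientations[[i]]) else orientations[[i]]
    list(duration_s = durations_s[[i]], gravity_dir = g,
         orientation = if (is.character(orientations)) orientations[[i]] else "custom")
  })
  structure(list(segments = segs, total_s = sum(durations_s)),
            class = "head_schedule")
}

#' Alternating schedule (e.g. half-day standing / half-day on the back)
#'
#' @param orientations two (or more) orientations to cycle through.
#' @param period_s duration of each segment, s.
#' @param horizon_s total horizon, s (must be a multiple of `period_s`).
#' @export
alternating_schedule <- function(orientations, period_s, horizon_s) {
  n <- round(horizon_s / period_s)
  stopifnot(abs(n * period_s - horizon_s) < 1e-6 * horizon_s)
  head_schedule(rep(orientations, length.out = n), rep(period_s, n))
}

#' Scenario configuration
#'
#' Bundles everything one simulation needs; see [run_scenario()].
#'
#' @param geometry a [limacon_params()] (default average eye).
#' @param spec boundary partition.
#' @param fp [flow_params()].
#' @param tp [transport_params()].
#' @param injection [injection_spec()].
#' @param schedule optional [head_schedule()]; `NULL` = constant
#'   gravity direction from `tp`.
#' @param horizon_days simulation horizon (default 30 days, one
#'   anti-VEGF injection interval).
#' @param h_mm target mesh edge length.
#' @param mode mesh mode; axisymmetric-2d is refused when the scenario
#'   breaks rotational symmetry.
#' @param macula_radius_mm radius of the macular region of interest.
#' @param label scenario name used in summaries.
#' @export
scenario_config <- function(geometry = default_eye_params(),
                            spec = default_boundary_spec(),
                            fp = flow_params(), tp = transport_params(),
                            injection = injection_spec(), schedule = NULL,
                            horizon_days = 30, h_mm = 1.1,
                            mode = "full-3d", macula_radius_mm = 2,
                            label = "scenario") {
  stopifnot(horizon_days > 0, h_mm > 0)
  cfg <- structure(list(geometry = geometry, spec = spec, fp = fp, tp = tp,
                        injection = injection, schedule = schedule,
                        horizon_days = horizon_days, h_mm = h_mm, mode = mode,
                        macula_radius_mm = macula_radius_mm, label = label),
                   class = "scenario_config")
  check_symmetry(cfg)
  cfg
}

check_symmetry <- function(cfg) {
  if (cfg$mode != "axisymmetric-2d") return(invisible(TRUE))
  bad <- abs(cfg$injection$psi_z_deg - 90) > 1e-9
  if (!is.null(cfg$schedule) || (cfg$tp$v_settle > 0 &&
                                 abs(abs(cfg$tp$gravity_dir[1]) - 1) > 1e-12))
    bad <- TRUE
  # an off-axis bolus breaks rotational symmetry unless it sits on the axis
  tip <- try(needle_tip_position(cfg$injection,
                                 build_domain(cfg$geometry, cfg$spec)),
             silent = TRUE)
  if (!inherits(tip, "try-error") && abs(tip[2]) + abs(tip[3]) > 0.25)
    bad <- TRUE   # bolus centre more than a quarter cell off the axis
  if (bad)
    stop("scenario breaks rotational symmetry (off-axis bolus, psi_z != 90, ",
         "or lateral gravity); use mode = 'full-3d'")
  invisible(TRUE)
}

#' Run one scenario end to end
#'
#' Geometry, mesh, Darcy flow, initial bolus, 30-day transport and the
#' therapy functionals.  Pass a precomputed `mesh`/`flow` to share them
#' across scenarios with identical geometry and flow parameters (e.g.
#' in [sweep_scenarios()]).
#'
#' @param cfg a [scenario_config()].
#' @param mesh,flow optional precomputed stages.
#' @param store_states keep concentration snapshots.
#' @param quiet suppress stage messages.
#' @return A `scenario_result`: the [advance()] run plus a one-row
#'   `summary` data frame (peak `J_M` and its time, `J_omega(T)`,
#'   `J_M_omega(T)`, `J_R(T)`, audit imbalance).
#' @export
run_scenario <- function(cfg, mesh = NULL, flow = NULL, store_states = FALSE,
                         quiet = TRUE) {
  stopifnot(inherits(cfg, "scenario_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dom <- build_domain(cfg$geometry, cfg$spec)
  if (is.null(mesh)) {
    say("[mesh] building %s mesh, h = %.3g mm", cfg$mode, cfg$h_mm)
    mesh <- build_mesh(dom, h = cfg$h_mm, mode = cfg$mode)
  }
  if (is.null(flow)) {
    say("[flow] assembling and solving the Darcy system")
    flow <- solve_darcy(assemble_darcy(mesh, cfg$fp))
  }
  tip <- needle_tip_position(cfg$injection, dom)
  say("[bolus] needle tip at (%.2f, %.2f, %.2f) mm", tip[1], tip[2], tip[3])
  C0 <- make_initial_bolus(mesh, tip, cfg$injection$bolus_radius_mm,
                           cfg$injection$dose_kg)
  say("[advance] %g days", cfg$horizon_days)
  run <- advance(C0, flow, cfg$tp, theta_scheme(), cfg$horizon_days * 86400,
                 mesh = mesh, schedule = cfg$schedule,
                 region = macula_region(dom$macula_center_mm,
                                        cfg$macula_radius_mm),
                 store_states = store_states)
  s <- run$series
  n <- nrow(s)
  summary <- data.frame(
    label = cfg$label,
    peak_J_M = run$peak_jm, peak_time_days = run$peak_time_days,
    J_omega_T = s$J_omega[n], J_M_omega_T = s$J_M_omega_cum[n],
    J_R_T = s$J_R[n],
    audit_imbalance = if (is.null(run$audit)) NA_real_ else run$audit$imbalance)
  structure(list(config = cfg, mesh = mesh, flow = flow, run = run,
                 tip_mm = tip, summary = summary),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s'\n", x$config$label))
  print(x$run)
  invisible(x)
}

#' Run and compare several scenarios
#'
#' All configurations must share geometry and horizon; mesh and flow
#' are computed once and reused when flow parameters agree.  Relative
#' differences are taken against a named baseline.
#'
#' @param cfgs list of [scenario_config()]s.
#' @param baseline index or label of the baseline scenario.
#' @return A `sweep_result`: long-format `table` of summaries with
#'   relative differences, and the individual results.
#' @export
sweep_scenarios <- function(cfgs, baseline = 1L) {
  stopifnot(length(cfgs) >= 2)
  hz <- vapply(cfgs, function(c) c$horizon_days, 0)
  if (length(unique(hz)) != 1)
    stop("sweep requires matching horizons")
  geo <- vapply(cfgs, function(c) paste(signif(unlist(c$geometry), 12),
                                        collapse = ","), "")
  if (length(unique(geo)) != 1)
    stop("sweep requires shared geometry")
  if (is.character(baseline))
    baseline <- match(baseline, vapply(cfgs, function(c) c$label, ""))
  stopifnot(!is.na(baseline), baseline >= 1, baseline <= length(cfgs))
  mesh <- NULL
  flow <- NULL
  flowkey <- ""
  res <- vector("list", length(cfgs))
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    if (is.null(mesh) || cfg$mode != mesh$mode ||
        abs(cfg$h_mm - mesh$h_mm) > 1e-12) {
      mesh <- build_mesh(build_domain(cfg$geometry, cfg$spec), h = cfg$h_mm,
                         mode = cfg$mode)
      flow <- NULL
    }
    fk <- paste(signif(unlist(cfg$fp[c("kappa", "mu", "Pv", "K_RCS", "L",
                                       "aqueous_production",
                                       "vitreous_fraction")]), 12),
                collapse = ",")
    if (is.null(flow) || fk != flowkey) {
      flow <- solve_darcy(assemble_darcy(mesh, cfg$fp))
      flowkey <- fk
    }
    res[[i]] <- run_scenario(cfg, mesh = mesh, flow = flow)
  }
  tab <- do.call(rbind, lapply(res, function(r) r$summary))
  base <- tab[baseline, ]
  relcols <- c("peak_J_M", "J_omega_T", "J_M_omega_T", "J_R_T")
  for (cc in relcols)
    tab[[paste0("rel_", cc)]] <- (tab[[cc]] - base[[cc]]) / base[[cc]]
  structure(list(table = tab, baseline = baseline, results = res),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Scenario sweep (baseline:", x$table$label[x$baseline], ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
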