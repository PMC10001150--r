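# Readers, writers, configuration and run manifests.

#' Write a mesh (with optional fields) as ASCII VTU
#'
#' XML UnstructuredGrid with tetrahedra (type 10) or triangles (type 5).
#' Boundary markers are attached as the cell field `boundary_id` on
#' request via `write_boundary_vtu()`.
#'
#' @param mesh an `eye_mesh`.
#' @param path output file (`.vtu`).
#' @param point_data named list of per-vertex scalar vectors or
#'   3-column matrices (vectors fields).
#' @param cell_data named list of per-cell scalars.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  nv <- nrow(mesh$vert)
  nc <- nrow(mesh$cell)
  d <- mesh$dim
  pts <- cbind(mesh$vert, matrix(0, nv, 3 - d))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(formatC(x, format = "g", digits = 9), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nc)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(pts, 1, num), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$cell - 1L, 1, function(r) paste(r, collapse = " ")), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(nc) * (d + 1L), collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(if (d == 3L) 10L else 5L, nc), collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <PointData>')
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.matrix(v)) {
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm)
      writeLines(apply(cbind(v, matrix(0, nrow(v), 3 - ncol(v))), 1, num), con)
    } else {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(num(v), con)
    }
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('      <CellData>')
  for (nm in names(cell_data)) {
    w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
    writeLines(num(cell_data[[nm]]), con)
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' @rdname write_vtu
#' @details `write_boundary_vtu()` writes the same mesh with the
#'   `boundary_id` cell field (1 = retina, 2 = lens, 3 = hyaloid;
#'   interior cells 0), identifying each cell by its marked facets.
#' @export
write_boundary_vtu <- function(mesh, path) {
  bid <- numeric(nrow(mesh$cell))
  bf <- mesh$boundary
  bid[mesh$facet_cell[bf, 1]] <- mesh$marker[bf]
  write_vtu(mesh, path, cell_data = list(boundary_id = bid))
}

#' Write a PVD time-series index referencing VTU files
#'
#' @param path `.pvd` output path.
#' @param vtu_paths character vector of VTU files (stored relative to
#'   the PVD's directory).
#' @param times_s time stamps, s.
#' @export
write_pvd <- function(path, vtu_paths, times_s) {
  stopifnot(length(vtu_paths) == length(times_s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="Collection" version="0.1">', con)
  writeLines('  <Collection>', con)
  for (i in seq_along(vtu_paths))
    writeLines(sprintf('    <DataSet timestep="%.10g" file="%s"/>',
                       times_s[i], basename(vtu_paths[i])), con)
  writeLines('  </Collection>', con)
  writeLines('</VTKFile>', con)
  invisible(path)
}

#' Write the functional time series CSV
#'
#' Columns `t_days,J_omega,J_M,J_M_omega_cum,J_R`.
#' @param series a `functional_series`.
#' @param path output CSV path.
#' @export
write_functional_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("t_days", "J_omega", "J_M",
                                             "J_M_omega_cum", "J_R")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flow summary CSV (total influx/outflux, max speed)
#' @param flow a `flow_field`.
#' @param path output CSV path.
#' @export
write_flow_summary_csv <- function(flow, path) {
  fl <- boundary_flux(flow)
  utils::write.csv(data.frame(
    influx_m3_s = -fl[["hyaloid"]],
    retina_outflux_m3_s = fl[["retina"]],
    max_speed_m_s = max(flow_speed(flow)),
    max_divergence_1_s = divergence_check(flow),
    schur_cg_iterations = flow$iterations), path, row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

config_schema <- list(
  geometry = c("q1", "q2", "q3", "mx", "us_csv"),
  boundary = c("lens_half", "hyaloid_width"),
  flow = c("kappa", "mu", "Pv", "K_RCS", "L", "aqueous_production",
           "vitreous_fraction", "c_pflow"),
  transport = c("D", "P", "k", "v_settle", "gravity_dir"),
  injection = c("limbus_distance_mm", "needle_depth_mm", "psi_xy_deg",
                "psi_z_deg", "bolus_radius_mm", "dose_kg"),
  schedule = c("orientations", "period_days"),
  run = c("horizon_days", "h_mm", "mode", "macula_radius_mm", "label",
          "seed"))

#' Load a scenario configuration from YAML
#'
#' Validates the schema (unknown keys are rejected with itemised
#' messages), applies unit sanity ranges (geometry in millimetres,
#' transport coefficients in SI), and returns a normalised
#' [scenario_config()].
#'
#' @param path YAML file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  errs <- character(0)
  for (sec in names(y)) {
    if (!sec %in% names(config_schema)) {
      errs <- c(errs, sprintf("unknown section '%s'", sec))
      next
    }
    bad <- setdiff(names(y[[sec]]), config_schema[[sec]])
    if (length(bad))
      errs <- c(errs, sprintf("unknown key(s) in '%s': %s", sec,
                              paste(bad, collapse = ", ")))
  }
  if (is.null(y$transport) || is.null(y$transport$D))
    errs <- c(errs, "missing required key 'transport.D' (diffusion, m^2/s)")
  g <- y$geometry
  if (!is.null(g$q1) && (g$q1 < 4 || g$q1 > 20))
    errs <- c(errs, sprintf(
      "geometry.q1 = %g is outside the sane vitreous range [4, 20] mm; geometry is specified in millimetres",
      g$q1))
  if (!is.null(y$transport$D) && is.numeric(y$transport$D) &&
      length(y$transport$D) == 1 && (y$transport$D <= 0 || y$transport$D > 1e-7))
    errs <- c(errs, sprintf(
      "transport.D = %g m^2/s is outside the plausible range (0, 1e-7]", y$transport$D))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  geom <- if (!is.null(g$us_csv)) {
    fit <- fit_limacon(read_us_points(g$us_csv))
    if (!fit$converged) stop("geometry fit did not converge for ", g$us_csv)
    fit$params
  } else limacon_params(g$q1 %||% 10, g$q2 %||% 1, g$q3 %||% 0.5,
                        g$mx %||% 0.5)
  spec <- do.call(boundary_spec, y$boundary %||% list())
  fp <- do.call(flow_params, y$flow %||% list())
  tpargs <- y$transport
  if (!is.null(tpargs$gravity_dir)) tpargs$gravity_dir <- unlist(tpargs$gravity_dir)
  if (is.list(tpargs$D)) tpargs$D <- matrix(unlist(tpargs$D), 3, 3)
  tp <- do.call(transport_params, tpargs)
  inj <- do.call(injection_spec, y$injection %||% list())
  run <- y$run %||% list()
  horizon_days <- run$horizon_days %||% 30
  sched <- if (!is.null(y$schedule))
    alternating_schedule(unlist(y$schedule$orientations),
                         y$schedule$period_days * 86400,
                         horizon_days * 86400)
  scenario_config(geometry = geom, spec = spec, fp = fp, tp = tp,
                  injection = inj, schedule = sched,
                  horizon_days = horizon_days,
                  h_mm = run$h_mm %||% 1.1, mode = run$mode %||% "full-3d",
                  macula_radius_mm = run$macula_radius_mm %||% 2,
                  label = run$label %||% tools::file_path_sans_ext(basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a scenario configuration back to YAML
#'
#' `load_config(dump_config(cfg, f))` reproduces `cfg` (normalised
#' round trip).
#' @param cfg a [scenario_config()].
#' @param path output path.
#' @export
dump_config <- function(cfg, path) {
  y <- list(
    geometry = cfg$geometry[c("q1", "q2", "q3", "mx")],
    boundary = unclass(cfg$spec),
    flow = cfg$fp[c("kappa", "mu", "Pv", "K_RCS", "L", "aqueous_production",
                    "vitreous_fraction")],
    transport = list(D = if (is.matrix(cfg$tp$D)) as.numeric(cfg$tp$D) else cfg$tp$D,
                     P = cfg$tp$P, k = cfg$tp$k, v_settle = cfg$tp$v_settle,
                     gravity_dir = cfg$tp$gravity_dir),
    injection = unclass(cfg$injection),
    run = list(horizon_days = cfg$horizon_days, h_mm = cfg$h_mm,
               mode = cfg$mode, macula_radius_mm = cfg$macula_radius_mm,
               label = cfg$label))
  if (!is.null(cfg$schedule)) {
    segs <- cfg$schedule$segments
    y$schedule <- list(
      orientations = vapply(segs, function(s) s$orientation, ""),
      period_days = segs[[1]]$duration_s / 86400)
  }
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  dump_config(cfg, f)
  unname(tools::md5sum(f))
}

#' Write all outputs of a scenario run
#'
#' CSV (functional series, summary, flow summary), VTU (final
#' concentration and flow; a time series plus PVD index if states were
#' stored) and a YAML run manifest with the configuration, its hash and
#' the package version.  Outputs of repeated runs of the same
#' configuration are bit-identical.
#'
#' @param result a `scenario_result` from [run_scenario()].
#' @param dir output directory (created if needed).
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  p <- function(f) file.path(dir, f)
  write_functional_csv(result$run$series, p("functionals.csv"))
  utils::write.csv(result$summary, p("summary.csv"), row.names = FALSE,
                   quote = FALSE)
  write_flow_summary_csv(result$flow, p("flow_summary.csv"))
  mesh <- result$mesh
  vel <- velocity_vertices(result$flow)
  write_vtu(mesh, p("final_state.vtu"),
            point_data = list(C_kg_m3 = result$run$C_final,
                              v_m_per_s = vel),
            cell_data = list(p_Pa = result$flow$P))
  write_boundary_vtu(mesh, p("mesh.vtu"))
  if (!is.null(result$run$states)) {
    files <- sprintf("state_%04d.vtu", seq_along(result$run$states) - 1L)
    for (i in seq_along(files))
      write_vtu(mesh, p(files[i]),
                point_data = list(C_kg_m3 = result$run$states[[i]]))
    write_pvd(p("trajectory.pvd"), file.path(dir, files), result$run$times_s)
  }
  dump_config(result$config, p("config.yaml"))
  manifest <- list(
    package = "eyevit",
    version = as.character(utils::packageVersion("eyevit")),
    config_hash = config_hash(result$config),
    mesh = list(mode = mesh$mode, vertices = nrow(mesh$vert),
                cells = nrow(mesh$cell), h_mm = mesh$h_mm),
    flow = list(schur_cg_iterations = result$flow$iterations,
                influx_m3_s = -boundary_flux(result$flow)[["hyaloid"]]),
    parameter_provenance = paste(
      "flow/transport defaults are literature-sourced (see",
      "inst/extdata/default_params.yaml and the methods vignette);",
      "c_pflow calibrated to the configured vitreous through-flow"),
    audit = result$run$audit[c("retina_out", "hyaloid_out", "imbalance")])
  tmp <- tempfile(tmpdir = dir)
  yaml::write_yaml(manifest, tmp, precision = 15L)
  file.rename(tmp, p("manifest.yaml"))   # atomic at run end
  invisible(dir)
}

# vertex-averaged velocity for export
velocity_vertices <- function(flow) {
  mesh <- flow$mesh
  nc <- nrow(mesh$cell)
  cent <- 0
  for (l in seq_len(mesh$dim + 1L))
    cent <- cent + mesh$vert[mesh$cell[, l], , drop = FALSE] / (mesh$dim + 1L)
  vc <- velocity_at(flow, seq_len(nc), cent)
  out <- matrix(0, nrow(mesh$vert), mesh$dim)
  cnt <- numeric(nrow(mesh$vert))
  for (l in seq_len(mesh$dim + 1L)) {
    idx <- mesh$cell[, l]
    for (cdim in seq_len(mesh$dim))
      out[, cdim] <- scatter_add(out[, cdim], idx, vc[, cdim])
    cnt <- scatter_add(cnt, idx, rep(1, nc))
  }
  out / pmax(cnt, 1)
}
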