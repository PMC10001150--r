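# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!is.null(.fx[[name]])) return(.fx[[name]])
  val <- switch(name,
    dom = build_domain(default_eye_params()),
    dom_circle = build_domain(limacon_params(10, 0, 0, 0)),
    ax_mesh = build_mesh(fx("dom"), h = 1.1, mode = "axisymmetric-2d"),
    ax_mesh_fine = build_mesh(fx("dom"), h = 0.6, mode = "axisymmetric-2d"),
    mesh3 = build_mesh(fx("dom"), h = 1.6, mode = "full-3d"),
    flow_ax = solve_darcy(assemble_darcy(fx("ax_mesh"))),
    flow3 = solve_darcy(assemble_darcy(fx("mesh3"))),
    stop("unknown fixture ", name))
  .fx[[name]] <- val
  val
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
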