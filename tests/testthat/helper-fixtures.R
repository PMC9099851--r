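# Shared fixtures: built once per test run, reused across files.
default_geom <- build_bifurcation()

kio_layout <- function(seed = 1) {
  place_struts(default_geom, "KIO", mix = c(0.79, 0.05, 0.16), seed = seed)
}

# one synthetic frame table for OCT tests
make_frames <- function(dmax, dmin = dmax, thrombus = 0,
                        in_bif = TRUE, proximal = TRUE) {
  data.frame(dmax_mm = dmax, dmin_mm = dmin,
             lumen_area_mm2 = pi * dmax * dmin / 4,
             thrombus_area_mm2 = rep_len(thrombus, length(dmax)),
             in_bifurcation = rep_len(in_bif, length(dmax)),
             proximal = rep_len(proximal, length(dmax)))
}

# lazily computed, shared across test files
.fixtures <- new.env()

sym_solution <- function() {
  if (is.null(.fixtures$sym)) {
    m <- generate_mesh(default_geom, NULL, mesh_config(0.25, 0.4))
    f <- solve_steady_flow(m, opts = solver_opts(picard_iters = 2))
    .fixtures$sym <- list(mesh = m, field = f)
  }
  .fixtures$sym
}
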