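#' Fluid properties of the working fluid
#'
#' Blood is modeled as an incompressible Newtonian liquid with density
#' 1060 kg/m^3 and dynamic viscosity 0.0035 Pa s.
#'
#' @param density_kg_m3 density (kg/m^3)
#' @param viscosity_pa_s dynamic viscosity (Pa s)
#' @return object of class `fluid_properties`
#' @export
fluid_properties <- function(density_kg_m3 = 1060, viscosity_pa_s = 0.0035) {
  if (density_kg_m3 <= 0 || viscosity_pa_s <= 0)
    stop("fluid_properties: density and viscosity must be > 0")
  structure(list(density = density_kg_m3, viscosity = viscosity_pa_s),
            class = "fluid_properties")
}

#' Flow boundary conditions
#'
#' Mean inlet velocity 0.14 m/s (200 mL/min through the 5.5 mm proximal
#' lumen), zero pressure at both outlets, rigid no-slip walls. The inlet
#' profile defaults to fully developed (parabolic); a plug option is kept
#' for sensitivity runs.
#'
#' @param u_mean_m_s mean inlet velocity (m/s)
#' @param profile "parabolic" or "plug"
#' @param outlet_pressure_pa outlet pressure (Pa); both outlets
#' @return object of class `flow_conditions`
#' @export
flow_conditions <- function(u_mean_m_s = 0.14,
                            profile = c("parabolic", "plug"),
                            outlet_pressure_pa = 0) {
  profile <- match.arg(profile)
  if (u_mean_m_s <= 0) stop("flow_conditions: mean velocity must be > 0")
  structure(list(u_mean = u_mean_m_s, profile = profile,
                 outlet_pressure = outlet_pressure_pa),
            class = "flow_conditions")
}

#' Nonlinear solver options
#'
#' @param tol relative nonlinear residual tolerance
#' @param max_iter maximum nonlinear iterations
#' @param picard_iters initial Picard (fixed-point) iterations before
#'   switching to Newton linearization
#' @param chord_rel relative-residual level below which chord (modified
#'   Newton) iterations reuse the last matrix factorization; raise it for
#'   warm-started solves whose initial linearization is already close
#' @param verbose print residual history
#' @return list of class `solver_opts`
#' @export
solver_opts <- function(tol = 1e-6, max_iter = 30, picard_iters = 3,
                        chord_rel = 0.03, verbose = FALSE) {
  structure(list(tol = tol, max_iter = max_iter,
                 picard_iters = picard_iters, chord_rel = chord_rel,
                 verbose = verbose),
            class = "solver_opts")
}

inlet_profile_values <- function(mesh, conds) {
  # parametrize inlet nodes across the inlet span; flow enters along the
  # inward normal of the (oriented) inlet boundary edges
  ied <- mesh$bedges[mesh$bedges$tag == "inlet", ]
  if (nrow(ied) == 0) stop("mesh has no inlet boundary")
  tvec <- mesh$nodes[ied$n2[1], ] - mesh$nodes[ied$n1[1], ]
  tvec <- tvec / sqrt(sum(tvec^2))
  dirv <- rot90(tvec)            # fluid lies left of the oriented edge
  inodes <- which(mesh$node_tag == "inlet")
  tall <- as.numeric(mesh$nodes[c(ied$n1, ied$n2), ] %*% tvec)
  t0 <- min(tall); t1 <- max(tall)
  ti <- as.numeric(mesh$nodes[inodes, , drop = FALSE] %*% tvec)
  xi <- (ti - t0) / (t1 - t0)
  mag <- if (conds$profile == "parabolic") 6 * conds$u_mean * xi * (1 - xi)
         else rep(conds$u_mean, length(xi))
  list(nodes = inodes, u = mag * dirv[1], v = mag * dirv[2], dir = dirv,
       width_mm = (t1 - t0))
}

#' Solve steady incompressible Navier-Stokes flow on a mesh
#'
#' Stabilized equal-order (P1-P1) finite-element discretization with
#' PSPG/PSPG-type pressure stabilization and streamline (SUPG) upwinding;
#' the nonlinear convection is resolved by Picard iterations followed by
#' Newton's method, with adaptive damping. The linearized saddle systems
#' are solved by sparse LU. Outlets carry the natural (do-nothing,
#' zero-pseudo-traction) condition, equivalent to zero outlet pressure.
#'
#' @param mesh a [generate_mesh()] mesh
#' @param fluid a [fluid_properties()]
#' @param conds a [flow_conditions()]
#' @param opts a [solver_opts()]
#' @param init optional initial state: a previous `flow_field` on the same
#'   mesh, or a list with nodal `u`, `v`, `p` vectors (warm start)
#' @return object of class `flow_field`: nodal velocities (m/s), pressure
#'   (Pa), residual history, convergence flag and boundary fluxes (m^2/s
#'   per unit depth)
#' @export
solve_steady_flow <- function(mesh, fluid = fluid_properties(),
                              conds = flow_conditions(),
                              opts = solver_opts(), init = NULL) {
  stopifnot(inherits(mesh, "bif_mesh"))
  n <- nrow(mesh$nodes)
  nodes_si <- mesh$nodes * 1e-3
  nu <- fluid$viscosity / fluid$density
  re <- fluid$density * conds$u_mean *
    (mesh$geom$params$d_prox * 1e-3) / fluid$viscosity
  if (re >= 2000)
    stop("solve_steady_flow: Reynolds number ", round(re),
         " is outside the laminar regime this solver targets")

  noslip <- mesh$node_tag %in% c("wall", "strut")
  inl <- inlet_profile_values(mesh, conds)
  isdir <- rep(FALSE, 3 * n)
  isdir[which(noslip)] <- TRUE
  isdir[n + which(noslip)] <- TRUE
  isdir[inl$nodes] <- TRUE
  isdir[n + inl$nodes] <- TRUE

  u <- numeric(n); v <- numeric(n); p <- numeric(n)
  if (!is.null(init)) {
    u <- init$u; v <- init$v
    p <- if (!is.null(init$p_kin)) init$p_kin else init$p / fluid$density
  }
  u[noslip] <- 0; v[noslip] <- 0
  u[inl$nodes] <- inl$u; v[inl$nodes] <- inl$v

  warm <- !is.null(init)
  res_scale <- if (warm) {
    # residual scale of the boundary-driven problem, so convergence means
    # the same thing for cold and warm starts
    u0 <- numeric(n); v0 <- numeric(n); p0 <- numeric(n)
    u0[inl$nodes] <- inl$u; v0[inl$nodes] <- inl$v
    a0 <- ns_assemble(nodes_si, mesh$tri, u0, v0, p0, nu, FALSE, isdir,
                      FALSE)
    max(sqrt(sum(a0$F^2)), 1e-300)
  } else NA_real_

  dirw <- which(isdir)
  res_hist <- numeric(0)
  res_prev <- Inf
  relax <- 1
  converged <- FALSE
  res0 <- NA_real_
  fac <- NULL
  refresh <- TRUE          # (re)factor the linearized operator this iter
  iters_since_fac <- 0
  for (it in seq_len(opts$max_iter)) {
    newton <- it > opts$picard_iters
    asm <- ns_assemble(nodes_si, mesh$tri, u, v, p, nu, newton, isdir,
                       refresh)
    F <- asm$F
    res <- sqrt(sum(F^2))
    if (it == 1) res0 <- if (warm) res_scale else max(res, 1e-300)
    rel <- res / res0
    res_hist <- c(res_hist, rel)
    if (opts$verbose)
      message(sprintf("  iter %2d %s%s rel.res %.3e", it,
                      if (newton) "newton" else "picard",
                      if (refresh) "*" else " ", rel))
    if (rel < opts$tol && it > 1) { converged <- TRUE; break }
    if (refresh) {
      A <- Matrix::sparseMatrix(
        i = c(asm$i, dirw), j = c(asm$j, dirw),
        x = c(asm$x, rep(1, length(dirw))), dims = c(3 * n, 3 * n))
      fac <- Matrix::lu(A)
      iters_since_fac <- 0
    }
    ratio <- res / res_prev
    if (res > 2 * res_prev) relax <- max(0.25, relax / 2)
    else relax <- min(1, relax * 1.5)
    res_prev <- res
    # refactor while far from the solution; near it, chord iterations
    # reuse the factorization until the contraction rate degrades
    refresh <- rel > opts$chord_rel ||
      (iters_since_fac >= 1 && ratio > 0.35)
    iters_since_fac <- iters_since_fac + 1
    dx <- as.numeric(Matrix::solve(fac, -F))
    u <- u + relax * dx[seq_len(n)]
    v <- v + relax * dx[n + seq_len(n)]
    p <- p + relax * dx[2 * n + seq_len(n)]
    if (it == opts$max_iter) break
  }
  if (!converged && res_hist[length(res_hist)] >= opts$tol) {
    cond <- structure(
      class = c("stentflow_solver_divergence", "error", "condition"),
      list(message = paste0(
        "solve_steady_flow: no convergence after ", opts$max_iter,
        " iterations (relative residual ",
        signif(res_hist[length(res_hist)], 3), ")"),
        call = sys.call(-1), residuals = res_hist))
    stop(cond)
  }

  fluxes <- boundary_fluxes(mesh, u, v)
  structure(list(u = u, v = v, p = p * fluid$density, p_kin = p,
                 residuals = res_hist, converged = TRUE,
                 fluxes = fluxes, reynolds = re,
                 fluid = fluid, conds = conds),
            class = "flow_field")
}

#' Boundary fluxes of a velocity field (m^2/s per unit depth)
#'
#' Integrates u.n over each tagged boundary (trapezoid rule, exact for the
#' P1 field); outward normals. The sum over all boundaries is the global
#' mass defect.
#'
#' @param mesh a `bif_mesh`
#' @param u,v nodal velocity components (m/s)
#' @return named list of fluxes per tag plus `net` and `net_relative`
#' @export
boundary_fluxes <- function(mesh, u, v) {
  be <- mesh$bedges
  p1 <- mesh$nodes[be$n1, , drop = FALSE] * 1e-3
  p2 <- mesh$nodes[be$n2, , drop = FALSE] * 1e-3
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  # fluid lies left of n1->n2, so the outward normal is (dy, -dx)
  fl <- 0.5 * ((u[be$n1] + u[be$n2]) * dy - (v[be$n1] + v[be$n2]) * dx)
  out <- lapply(split(fl, be$tag), sum)
  net <- sum(fl)
  inflow <- abs(out$inlet)
  c(out, list(net = net,
              net_relative = if (inflow > 0) abs(net) / inflow else 0))
}

#' Shear-rate magnitude field from a converged flow solution
#'
#' Element-wise shear rate gamma = sqrt(2 D:D) (1/s) with D the symmetric
#' part of the velocity gradient, from the recovered P1 gradients.
#'
#' @param field a converged [solve_steady_flow()] field
#' @param mesh the mesh the field was solved on
#' @return object of class `shear_field`: `gamma` (1/s), `area_mm2`,
#'   element centroids (mm)
#' @export
compute_shear_rate_field <- function(field, mesh) {
  stopifnot(inherits(field, "flow_field"))
  if (!isTRUE(field$converged))
    stop("compute_shear_rate_field: field is not converged")
  sr <- shear_rate_elements(mesh$nodes * 1e-3, mesh$tri, field$u, field$v)
  structure(list(gamma = sr$gamma, area_mm2 = mesh$areas_mm2,
                 cx = sr$cx * 1e3, cy = sr$cy * 1e3),
            class = "shear_field")
}

#' Interpolate a flow field at arbitrary points
#'
#' @param mesh a `bif_mesh`
#' @param field a `flow_field`
#' @param pts_mm query points (mm), n x 2
#' @return data frame with u, v (m/s) and speed; NA outside the mesh
#' @export
probe_velocity <- function(mesh, field, pts_mm) {
  if (is.null(dim(pts_mm))) pts_mm <- matrix(pts_mm, ncol = 2)
  loc <- locate_points(mesh$nodes, mesh$tri, pts_mm)
  ok <- loc$tri > 0
  u <- v <- rep(NA_real_, nrow(pts_mm))
  if (any(ok)) {
    tv <- mesh$tri[loc$tri[ok], , drop = FALSE]
    w <- loc$bary[ok, , drop = FALSE]
    u[ok] <- rowSums(w * matrix(field$u[tv], ncol = 3))
    v[ok] <- rowSums(w * matrix(field$v[tv], ncol = 3))
  }
  data.frame(u = u, v = v, speed = sqrt(u^2 + v^2))
}

#' Centre-line velocity of the proximal segment
#'
#' Speed at the mid-proximal point on the segment axis; the quantity
#' monitored by the mesh-convergence study.
#'
#' @param mesh a `bif_mesh`
#' @param field a `flow_field`
#' @return speed (m/s)
#' @export
centerline_velocity <- function(mesh, field) {
  g <- mesh$geom
  xc <- if (!is.null(g$tracks)) {
    c(g$frames$J[1] - g$params$len_prox / 2, g$frames$J[2])
  } else {
    c(g$params$len_prox / 2, 0)
  }
  probe_velocity(mesh, field, xc)$speed
}

#' Mesh-convergence study
#'
#' Solves the same configuration on successively refined meshes and reports
#' the monitored quantities (centre-line velocity and high-shear area) and
#' their successive relative changes.
#'
#' @param geom geometry
#' @param layout optional strut layout
#' @param cfg base [mesh_config()]; its `h_max` is the coarsest level
#' @param levels number of refinement levels (>= 2), each shrinking h_max
#'   by `ratio`; alternatively a numeric vector of explicit h_max values
#' @param ratio refinement ratio between levels
#' @param fluid,conds,opts solver setup
#' @param gamma_c high-shear threshold (1/s)
#' @param roi region of interest for the high-shear area (see
#'   [compute_shear_metrics()])
#' @return data frame: h, elements, centerline velocity, A_high, and
#'   successive relative changes
#' @export
convergence_study <- function(geom, layout = NULL, cfg = mesh_config(0.3),
                              levels = 3, ratio = sqrt(2),
                              fluid = fluid_properties(),
                              conds = flow_conditions(),
                              opts = solver_opts(), gamma_c = 1000,
                              roi = "whole-domain") {
  hs <- if (length(levels) > 1) as.numeric(levels)
        else {
          if (levels < 2) stop("convergence_study: need at least 2 levels")
          cfg$h_max / ratio^(seq_len(levels) - 1)
        }
  rows <- lapply(hs, function(h) {
    m <- generate_mesh(geom, layout,
                       mesh_config(h, cfg$near_wall_factor))
    f <- solve_steady_flow(m, fluid, conds, opts)
    sf <- compute_shear_rate_field(f, m)
    sm <- compute_shear_metrics(sf, gamma_c = gamma_c, roi = roi)
    data.frame(h = h, elements = nrow(m$tri),
               centerline_velocity = centerline_velocity(m, f),
               a_high_mm2 = sm$a_high_mm2, shear_max = sm$shear_max)
  })
  out <- do.call(rbind, rows)
  out$dv_rel <- c(NA, abs(diff(out$centerline_velocity)) /
                    pmax(out$centerline_velocity[-nrow(out)], 1e-300))
  out$da_rel <- c(NA, abs(diff(out$a_high_mm2)) /
                    pmax(out$a_high_mm2[-nrow(out)], 1e-300))
  out
}
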