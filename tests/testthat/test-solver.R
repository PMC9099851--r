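# plane-Poiseuille closed form: centerline velocity 1.5 U, wall shear 6U/h
test_that("solver reproduces plane Poiseuille flow", {
  ch <- build_channel(5.5, 15)
  m <- generate_mesh(ch, NULL, mesh_config(5.5 / 20))
  f <- solve_steady_flow(m, opts = solver_opts(picard_iters = 2))
  u_c <- centerline_velocity(m, f)
  expect_lt(abs(u_c - 1.5 * 0.14) / (1.5 * 0.14), 0.01)
  sf <- compute_shear_rate_field(f, m)
  wall_adj <- abs(sf$cy) > 2.75 - 0.25 * 0.275
  gw <- max(sf$gamma[wall_adj])
  expect_lt(abs(gw - 6 * 0.14 / 0.0055) / (6 * 0.14 / 0.0055), 0.05)
  # exact global mass balance
  expect_lt(f$fluxes$net_relative, 1e-8)
})

test_that("shear-rate definition: rigid motion gives zero, linear shear k", {
  ch <- build_channel(2, 4)
  m <- generate_mesh(ch, NULL, mesh_config(0.2))
  n <- nrow(m$nodes)
  rigid <- structure(list(u = rep(0.3, n), v = rep(-0.1, n),
                          converged = TRUE), class = "flow_field")
  sf0 <- compute_shear_rate_field(rigid, m)
  expect_lt(max(sf0$gamma), 1e-9)
  k <- 37.5
  lin <- structure(list(u = k * m$nodes[, 2] * 1e-3, v = rep(0, n),
                        converged = TRUE), class = "flow_field")
  sf1 <- compute_shear_rate_field(lin, m)
  expect_equal(sf1$gamma, rep(k, nrow(m$tri)), tolerance = 1e-9)
})

test_that("vanishing inlet velocity gives a vanishing field", {
  ch <- build_channel(5.5, 10)
  m <- generate_mesh(ch, NULL, mesh_config(0.4))
  f <- solve_steady_flow(m, conds = flow_conditions(u_mean_m_s = 1e-8),
                         opts = solver_opts(picard_iters = 2))
  expect_lt(max(abs(f$u)), 2e-8)
  expect_lt(max(abs(f$p)), 1e-3)
})

test_that("creeping-flow limit matches a pure Stokes solve", {
  # at U scaled by 1e-3 (Re ~ 0.2) the converged nonlinear solution and
  # the first (Stokes) iterate differ by less than 0.1%
  ch <- build_channel(5.5, 10)
  m <- generate_mesh(ch, NULL, mesh_config(0.3))
  conds <- flow_conditions(u_mean_m_s = 0.14e-3)
  f_full <- solve_steady_flow(m, conds = conds,
                              opts = solver_opts(picard_iters = 2))
  f_stokes <- solve_steady_flow(m, conds = conds,
                                opts = solver_opts(tol = 0.9,
                                                   max_iter = 2,
                                                   picard_iters = 2))
  scale <- max(abs(f_full$u))
  expect_lt(max(abs(f_full$u - f_stokes$u)) / scale, 1e-3)
  expect_lt(max(abs(f_full$v - f_stokes$v)) / scale, 1e-3)
})

test_that("solution is invariant under mesh-node reordering", {
  ch <- build_channel(5.5, 10)
  m <- generate_mesh(ch, NULL, mesh_config(0.35))
  f1 <- solve_steady_flow(m, opts = solver_opts(picard_iters = 2))
  set.seed(5)
  perm <- sample(nrow(m$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- m
  m2$nodes <- m$nodes[perm, ]
  m2$tri <- matrix(inv[m$tri], ncol = 3)
  m2$bedges$n1 <- inv[m$bedges$n1]
  m2$bedges$n2 <- inv[m$bedges$n2]
  m2$node_tag <- m$node_tag[perm]
  f2 <- solve_steady_flow(m2, opts = solver_opts(picard_iters = 2))
  expect_lt(max(abs(f2$u[inv] - f1$u)) / max(abs(f1$u)), 1e-6)
})

test_that("turbulent-regime inputs and divergence are explicit failures", {
  ch <- build_channel(5.5, 10)
  m <- generate_mesh(ch, NULL, mesh_config(0.4))
  expect_error(solve_steady_flow(m, conds = flow_conditions(5)),
               "laminar")
  err <- tryCatch(
    solve_steady_flow(m, opts = solver_opts(tol = 1e-14, max_iter = 3)),
    stentflow_solver_divergence = function(e) e)
  expect_s3_class(err, "stentflow_solver_divergence")
  expect_true(length(err$residuals) >= 3)
  # an unconverged field is never silently consumed downstream
  fake <- structure(list(u = 1, v = 1, converged = FALSE),
                    class = "flow_field")
  expect_error(compute_shear_rate_field(fake, m), "not converged")
})

test_that("symmetric strut-free bifurcation splits the outflow evenly", {
  sol <- sym_solution()
  f <- sol$field
  q_mb <- f$fluxes$outlet_mb
  q_sb <- f$fluxes$outlet_sb
  expect_lt(abs(q_mb - q_sb) / (q_mb + q_sb), 0.005)
  expect_lt(f$fluxes$net_relative, 1e-8)
})

test_that("mesh convergence study reports levels and relative changes", {
  ch <- build_channel(5.5, 15)
  out <- convergence_study(build_channel(5.5, 15), NULL,
                           mesh_config(0.4), levels = 3)
  expect_identical(nrow(out), 3L)
  # centerline velocity settles on the Poiseuille value at the finest level
  expect_lt(abs(out$centerline_velocity[3] - 0.21) / 0.21, 0.01)
  expect_lt(out$dv_rel[3], 0.01)
  expect_error(convergence_study(ch, NULL, mesh_config(0.4), levels = 1),
               "at least 2")
  # identical h at two levels reports zero change
  same <- convergence_study(ch, NULL, mesh_config(0.4),
                            levels = c(0.4, 0.4))
  expect_equal(same$dv_rel[2], 0)
})
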