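test_that("channel widths equal the requested diameters exactly", {
  g <- default_geom
  v <- g$vertices
  # proximal: vertical distance between the two horizontal walls
  expect_equal(unname(v["inlet_upper", 2] - v["inlet_lower", 2]), 5.5,
               tolerance = 1e-12)
  # branch widths: outlet corner separations projected on the wall normal
  w_mb <- sqrt(sum((v["mb_outlet_outer", ] - v["mb_outlet_inner", ])^2))
  w_sb <- sqrt(sum((v["sb_outlet_outer", ] - v["sb_outlet_inner", ])^2))
  expect_lt(abs(w_mb - 3.5), 1e-9)
  expect_lt(abs(w_sb - 3.5), 1e-9)
})

test_that("equal branch diameters and angles give a mirror-symmetric lumen", {
  g <- default_geom
  v <- g$vertices
  mirror <- function(p) c(p[1], 2 * g$frames$J[2] - p[2])
  expect_equal(unname(v["ostium_prox_corner", ]),
               mirror(v["prox_upper_corner", ]), tolerance = 1e-9)
  expect_equal(unname(v["sb_outlet_outer", ]),
               mirror(v["mb_outlet_outer", ]), tolerance = 1e-9)
  expect_equal(unname(v["sb_outlet_inner", ]),
               mirror(v["mb_outlet_inner", ]), tolerance = 1e-9)
})

test_that("degenerate and invalid parameters are rejected", {
  expect_error(bif_params(angle_mb_sb = 0), "angle")
  expect_error(bif_params(d_prox = -1), "length|diameter")
  expect_error(bif_params(d_prox = 3.0, d_mb = 3.5), "proximal")
  expect_error(bif_params(angle_branch_prox = 180), "degenerate")
  expect_error(build_bifurcation(bif_params(len_mb = 2)),
               "too short")
})

test_that("ostium segment spans the SB mouth with the configured width", {
  g <- default_geom
  expect_equal(g$ostium$length, 3.5, tolerance = 1e-12)
  # both endpoints lie on the lumen boundary
  v <- g$vertices
  nv <- nrow(v)
  segs <- cbind(v[, 1], v[, 2], v[c(2:nv, 1), 1], v[c(2:nv, 1), 2])
  d1 <- min(dist_to_segments(matrix(g$ostium$p1, 1), segs))
  d2 <- min(dist_to_segments(matrix(g$ostium$p2, 1), segs))
  expect_lt(d1, 1e-9)
  expect_lt(d2, 1e-9)
})

test_that("polygon area matches a Monte-Carlo point-in-polygon estimate", {
  g <- default_geom
  a_exact <- polygon_area(g$vertices)
  set.seed(101)
  bb <- apply(g$vertices, 2, range)
  n <- 4e5
  pts <- cbind(runif(n, bb[1, 1], bb[2, 1]), runif(n, bb[1, 2], bb[2, 2]))
  a_mc <- mean(point_in_polygon(pts, g$vertices)) *
    prod(bb[2, ] - bb[1, ])
  expect_lt(abs(a_mc - a_exact) / a_exact, 0.005)
})

test_that("inlet velocity reproduces the study flow conditions", {
  u <- inlet_velocity_from_flow(200, 5.5)
  expect_equal(round(u, 2), 0.14)
  expect_equal(u, 0.1403, tolerance = 1e-3)
  # linear in Q
  expect_equal(inlet_velocity_from_flow(400, 5.5), 2 * u,
               tolerance = 1e-12)
  expect_equal(inlet_velocity_from_flow(400, 5.5), 0.2807,
               tolerance = 1e-3)
  # vanishing-flow limit and input validation
  expect_lt(inlet_velocity_from_flow(1e-9, 5.5), 1e-10)
  expect_error(inlet_velocity_from_flow(0, 5.5), "positive")
  expect_error(inlet_velocity_from_flow(200, -1), "positive")
})
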