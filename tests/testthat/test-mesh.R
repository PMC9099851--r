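test_that("mesh element areas reproduce the fluid-domain area exactly", {
  ch <- build_channel(5.5, 15)
  m <- generate_mesh(ch, NULL, mesh_config(h_max = 0.275))
  expect_lt(abs(sum(m$areas_mm2) - 82.5) / 82.5, 1e-6)
  expect_true(all(m$areas_mm2 > 0))
})

test_that("halving h_max grows the element count about fourfold", {
  ch <- build_channel(5.5, 15)
  # uniform sizing isolates the 2D area scaling from the near-wall bands
  m1 <- generate_mesh(ch, NULL, mesh_config(0.5, near_wall_factor = 1))
  m2 <- generate_mesh(ch, NULL, mesh_config(0.25, near_wall_factor = 1))
  ratio <- nrow(m2$tri) / nrow(m1$tri)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
})

test_that("no element edge exceeds h_max and near-wall edges are refined", {
  m <- generate_mesh(default_geom, kio_layout(1), mesh_config(0.3))
  expect_lte(max_edge_length(m), 0.3 + 1e-9)
  # boundary edges along walls/struts obey the near-wall refinement
  be <- m$bedges[m$bedges$tag %in% c("wall", "strut"), ]
  blen <- sqrt(rowSums((m$nodes[be$n1, ] - m$nodes[be$n2, ])^2))
  expect_lte(max(blen), 0.25 * 0.3 + 1e-9)
})

test_that("every boundary edge carries exactly one tag and all tags appear", {
  m <- generate_mesh(default_geom, kio_layout(1), mesh_config(0.3))
  expect_false(anyNA(m$bedges$tag))
  expect_setequal(unique(m$bedges$tag),
                  c("inlet", "outlet_mb", "outlet_sb", "wall", "strut"))
})

test_that("mesh generation is deterministic", {
  cfg <- mesh_config(0.3)
  m1 <- generate_mesh(default_geom, kio_layout(5), cfg)
  m2 <- generate_mesh(default_geom, kio_layout(5), cfg)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tri, m2$tri)
})

test_that("default bifurcation with struts meshes at the reference density", {
  m <- generate_mesh(default_geom, kio_layout(1), mesh_config(0.1))
  expect_gt(nrow(m$tri), 5e4)
  expect_lt(nrow(m$tri), 2e5)
})

test_that("degenerate strut-wall slivers are reported with the strut id", {
  lay <- kio_layout(3)
  # force one malapposed strut to hover a few microns off the lower wall
  i <- which(lay$struts$apposition == "MA")[1]
  half <- lay$spec$thickness_um / 2000
  lay$struts$y[i] <- -2.75 + half + 0.004   # 4 um gap
  lay$struts$x[i] <- -6
  lay$struts$tx[i] <- -1; lay$struts$ty[i] <- 0
  expect_error(generate_mesh(default_geom, lay, mesh_config(0.15)),
               "sliver")
})

test_that("overly coarse meshes are refused", {
  expect_error(generate_mesh(build_channel(3.5, 10), NULL,
                             mesh_config(0.4)),
               "one tenth")
})
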