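fake_shear <- function(gamma, area = rep(0.01, length(gamma)),
                       cx = seq_along(gamma), cy = rep(0, length(gamma))) {
  structure(list(gamma = gamma, area_mm2 = area, cx = cx, cy = cy),
            class = "shear_field")
}

test_that("sub-threshold fields have zero high-shear area", {
  sm <- compute_shear_metrics(fake_shear(rep(500, 100)))
  expect_identical(sm$a_high_mm2, 0)
  expect_identical(sm$shear_max, 500)
})

test_that("a constructed high-shear patch is measured exactly", {
  g <- c(rep(100, 50), rep(1500, 5))
  a <- c(rep(0.02, 50), rep(0.01, 5))
  sm <- compute_shear_metrics(fake_shear(g, a))
  expect_equal(sm$a_high_mm2, 0.05)
  expect_identical(sm$shear_max, 1500)
})

test_that("high-shear area is monotone non-increasing in the threshold", {
  set.seed(3)
  sf <- fake_shear(rexp(500, 1 / 800), area = runif(500, 0.005, 0.02))
  thresholds <- c(200, 500, 1000, 2000, 4000)
  a <- vapply(thresholds, function(tc)
    compute_shear_metrics(sf, gamma_c = tc)$a_high_mm2, numeric(1))
  expect_true(all(diff(a) <= 0))
})

test_that("region of interest uses centroid membership", {
  sf <- fake_shear(c(2000, 2000), area = c(0.01, 0.02),
                   cx = c(0, 10), cy = c(0, 0))
  sm <- compute_shear_metrics(sf, roi = list(center = c(0, 0), radius = 1))
  expect_equal(sm$a_high_mm2, 0.01)     # only the in-window element
  expect_error(compute_shear_metrics(sf, roi = list(center = c(99, 99),
                                                    radius = 0.1)),
               "empty")
  # polygon windows are accepted too
  sm2 <- compute_shear_metrics(sf, roi = rbind(c(-1, -1), c(1, -1),
                                               c(1, 1), c(-1, 1)))
  expect_equal(sm2$a_high_mm2, 0.01)
})

test_that("the default ostium window sits on the SB mouth", {
  roi <- ostium_roi(default_geom)
  expect_equal(roi$radius, 3.5)
  expect_equal(roi$center, default_geom$ostium$center)
  expect_error(ostium_roi(build_channel(5, 10)), "no ostium")
})

test_that("strut-free bifurcation flow stays below the high-shear threshold", {
  # per-segment wall shear 6U/h with the split fluxes lies at 150-190 1/s,
  # far below 1000; only the sharp carina apex can locally exceed it
  sol <- sym_solution()
  sf <- compute_shear_rate_field(sol$field, sol$mesh)
  sm <- compute_shear_metrics(sf)
  expect_lt(sm$a_high_mm2, 0.01)
  # wall shear in the straight segments matches 6U/h per segment
  prox_wall <- sf$cx < -8 & abs(sf$cy) > 2.75 - 0.1
  g_wall <- max(sf$gamma[prox_wall])
  expect_lt(abs(g_wall - 152.7) / 152.7, 0.1)
})
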