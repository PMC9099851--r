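test_that("strut classification follows the protrusion rule with a strict boundary", {
  st <- data.frame(wall_gap_um = c(0, 100, 81, 81),
                   in_ostium = c(FALSE, FALSE, FALSE, TRUE),
                   thickness_um = 81)
  cls <- classify_struts(st)
  # gap 0 -> WA; 100 > 81 -> MA; exactly 81 -> WA (strictly greater); ostium -> floating
  expect_identical(c(cls$n_wa, cls$n_ma, cls$n_floating), c(2L, 1L, 1L))
})

test_that("counts and percentages match the counting oracle", {
  st <- data.frame(
    wall_gap_um = c(rep(0, 32), rep(120, 2), rep(NA, 6)),
    in_ostium = c(rep(FALSE, 34), rep(TRUE, 6)),
    thickness_um = 81)
  cls <- classify_struts(st)
  expect_identical(c(cls$n_wa, cls$n_ma, cls$n_floating), c(32L, 2L, 6L))
  expect_equal(c(cls$pct_wa, cls$pct_ma, cls$pct_floating),
               c(80, 5, 15))
})

test_that("pullbacks without strut records give zero counts, not an error", {
  cls <- classify_struts(data.frame())
  expect_identical(cls$total, 0L)
  expect_true(is.na(cls$pct_wa))
})

test_that("elliptical index is the mean per-frame Dmax/Dmin ratio", {
  expect_equal(elliptical_index(make_frames(rep(5.5, 10)))$ei, 1.0)
  # the published KIO worked example: printed Max/Min diameters
  ei <- elliptical_index(make_frames(5.75, 5.40))$ei
  expect_equal(ei, 5.75 / 5.40, tolerance = 1e-12)
  expect_equal(round(ei, 2), 1.06)
  # arithmetic mean over frames
  fr <- make_frames(c(1.02, 1.08), c(1, 1))
  expect_equal(elliptical_index(fr)$ei, 1.05)
  # global variant: extreme ratio across frames
  expect_equal(elliptical_index(fr, method = "global")$ei, 1.08)
  expect_error(elliptical_index(make_frames(5, 0)), "Dmin")
})

test_that("elliptical index is at least 1 and exactly 1 only when circular", {
  set.seed(8)
  for (i in 1:20) {
    d <- runif(12, 3, 6)
    r <- 1 + abs(rnorm(12, 0, 0.05))
    fr <- make_frames(d * sqrt(r), d / sqrt(r))
    expect_gte(elliptical_index(fr)$ei, 1)
  }
})

test_that("top-3 thrombus averaging matches the sorting oracle", {
  fr <- make_frames(rep(3.5, 4), thrombus = c(0.1, 0.5, 0.7, 0.9))
  expect_equal(thrombus_area_top3(fr), 0.7)
  expect_equal(thrombus_area_top3(make_frames(rep(3.5, 5), thrombus = 0)), 0)
  set.seed(21)
  x <- rexp(1000, 2)
  fr2 <- make_frames(rep(3.5, 1000), thrombus = x)
  brute <- mean(x[order(x, decreasing = TRUE)][1:3])
  expect_identical(thrombus_area_top3(fr2), brute)
  # permutation invariance
  fr3 <- fr2[sample(1000), ]
  expect_identical(thrombus_area_top3(fr3), brute)
  expect_warning(thrombus_area_top3(make_frames(rep(3, 2),
                                                thrombus = c(1, 2))),
                 "fewer than 3")
  expect_error(thrombus_area_top3(make_frames(numeric(0))), "no bifurcation")
})

test_that("proximal summary returns diameter extrema and lumen area", {
  fr <- make_frames(rep(5.5, 6))
  ps <- proximal_summary(fr)
  expect_equal(c(ps$d_min, ps$d_mean, ps$d_max), c(5.5, 5.5, 5.5))
  expect_equal(ps$lumen_area_mm2, pi * 2.75^2, tolerance = 1e-9)
  fr2 <- make_frames(c(5.2, 5.8))
  ps2 <- proximal_summary(fr2)
  expect_equal(c(ps2$d_min, ps2$d_mean, ps2$d_max), c(5.2, 5.5, 5.8))
  ps3 <- proximal_summary(make_frames(5.1))
  expect_equal(ps3$d_min, ps3$d_max)
})

test_that("pullback configuration encodes the acquisition protocol", {
  pc <- pullback_config()
  expect_equal(pc$frame_interval_mm * pc$n_frames, 54)
  expect_equal(pc$analysis_stride * pc$frame_interval_mm, 1)
})
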