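test_that("a coarse end-to-end run produces a complete report", {
  cfg <- run_config(cohort = cohort_config(n_per_group = 2, seed = 77),
                    mesh = mesh_config(0.3, near_wall_factor = 0.6),
                    solver = solver_opts(tol = 1e-5, picard_iters = 0,
                                         chord_rel = 0.5))
  rep <- run_study(cfg)
  expect_s3_class(rep, "study_report")
  expect_identical(nrow(rep$metrics), 6L)
  expect_setequal(unique(rep$metrics$group), c("KIO", "KBI", "BD-DES"))
  expect_gte(length(rep$stats), 6)
  expect_true(all(rep$metrics$cfd_converged))
  expect_true(all(is.finite(rep$metrics$a_high_roi_mm2)))
  # provenance is embedded
  expect_match(rep$provenance$config_hash, "^[0-9a-f]+$")
  expect_identical(rep$provenance$seed, 77L)
})

test_that("study reports are deterministic given seed and config", {
  cfg <- run_config(cohort = cohort_config(n_per_group = 3, seed = 9),
                    do_cfd = FALSE)
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$provenance$config_hash, r2$provenance$config_hash)
})

test_that("tables follow the median (IQR) convention and rounding rules", {
  expect_identical(fmt_median_iqr(3, 2, 4, digits = 0), "3 (2–4)")
  expect_identical(fmt_median_iqr(5, 5, 5, digits = 0), "5 (5–5)")
  expect_identical(fmt_median_iqr(1.056, 1.01, 1.1, digits = 2),
                   "1.06 (1.01–1.10)")
  cfg <- run_config(cohort = cohort_config(n_per_group = 5, seed = 2),
                    do_cfd = FALSE)
  tb <- render_tables(run_study(cfg))
  expect_true(all(c("metric", "KIO", "KBI", "BD-DES", "p_value") %in%
                    names(tb)))
  # percentages at 1 decimal, counts as integers, mm at 2 decimals
  pctrow <- tb[tb$metric == "pct_floating", "KIO"]
  expect_match(pctrow, "^\\d+\\.\\d \\(")
  cntrow <- tb[tb$metric == "damage_cat1", "KIO"]
  expect_match(cntrow, "^\\d+ \\(")
  eirow <- tb[tb$metric == "ei", "KIO"]
  expect_match(eirow, "^\\d\\.\\d{2} \\(")
})

test_that("group subsetting restricts the cohort", {
  cfg <- run_config(cohort = cohort_config(n_per_group = 2, seed = 4),
                    groups = c("KIO", "KBI"), do_cfd = FALSE)
  rep <- run_study(cfg)
  expect_setequal(unique(rep$metrics$group), c("KIO", "KBI"))
  expect_error(run_study(run_config(groups = "nope", do_cfd = FALSE)),
               "no groups")
})
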