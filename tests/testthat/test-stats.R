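# independent H computation used as the oracle throughout this file
h_oracle <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  sums <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(sums^2 / ns) - 3 * (n + 1)
  tie <- table(values)
  h / (1 - sum(tie^3 - tie) / (n^3 - n))
}

test_that("median and IQR use linear-interpolation quantiles", {
  expect_equal(unname(median_iqr(1:5)), c(3, 2, 4))
  expect_equal(unname(median_iqr(7)), c(7, 7, 7))
  x <- c(0.17, 0.52, 0.65, 0.4, 0.6)
  expect_equal(median_iqr(x)[["median"]], sort(x)[3])
  expect_equal(median_iqr(x)[["median"]], 0.52)
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("identical observations give H = 0 and p = 1", {
  kt <- kruskal_wallis(rep(4, 9), rep(c("a", "b", "c"), each = 3))
  expect_identical(kt$h, 0)
  expect_identical(kt$p, 1)
})

test_that("exact permutation p matches full enumeration on n = (2,2,2)", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("a", "b", "c"), each = 2)
  kt <- kruskal_wallis(vals, grp)
  expect_equal(kt$h, h_oracle(vals, grp), tolerance = 1e-12)
  # oracle: enumerate every ordering of the values over fixed positions
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  hs <- vapply(perms(vals), function(vv) h_oracle(vv, grp), numeric(1))
  p_enum <- mean(hs >= kt$h - 1e-12)
  expect_equal(kt$p_exact, p_enum, tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis is the squared-normal Mann-Whitney", {
  set.seed(2)
  x <- rnorm(14); g <- rep(c("a", "b"), c(6, 8))
  kt <- kruskal_wallis(x, g)
  wt <- stats::wilcox.test(x[g == "a"], x[g == "b"], exact = FALSE,
                           correct = FALSE)
  expect_equal(kt$p, wt$p.value, tolerance = 1e-10)
})

test_that("H is invariant under group-label permutation", {
  set.seed(6)
  x <- rnorm(15); g <- rep(c("a", "b", "c"), each = 5)
  h1 <- kruskal_wallis(x, g)$h
  relab <- c(a = "c", b = "a", c = "b")[g]
  expect_equal(kruskal_wallis(x, relab)$h, h1, tolerance = 1e-12)
})

test_that("Dunn's test is gated on the omnibus p-value", {
  x <- c(1, 2, 10, 11, 100, 101)
  g <- rep(c("a", "b", "c"), each = 2)
  expect_error(dunn_test(x, g, p_kw = 0.3), "gated")
})

test_that("Dunn z and p match hand rank arithmetic on separated groups", {
  # ranks 1..6 in three separated pairs: rank means 1.5, 3.5, 5.5;
  # se = sqrt((6*7/12)(1/2+1/2)) = sqrt(3.5); z_ac = -4/sqrt(3.5)
  x <- c(1, 2, 10, 11, 100, 101)
  g <- rep(c("a", "b", "c"), each = 2)
  dn <- dunn_test(x, g, p_kw = 0.01)
  z_ac <- -4 / sqrt(3.5)
  row_ac <- dn$pairs[dn$pairs$group1 == "a" & dn$pairs$group2 == "c", ]
  expect_equal(row_ac$z, z_ac, tolerance = 1e-12)
  expect_equal(row_ac$p, 2 * pnorm(z_ac), tolerance = 1e-12)
  row_ab <- dn$pairs[dn$pairs$group1 == "a" & dn$pairs$group2 == "b", ]
  expect_equal(row_ab$z, -2 / sqrt(3.5), tolerance = 1e-12)
  expect_equal(dn$pairs$p_bonferroni, pmin(1, dn$pairs$p * 3))
})

test_that("a duplicated group yields z = 0 and p = 1 for that pair", {
  x <- c(1, 2, 3, 1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  dn <- dunn_test(x, g, p_kw = 0.01)
  row_ab <- dn$pairs[dn$pairs$group1 == "a" & dn$pairs$group2 == "b", ]
  expect_equal(row_ab$z, 0, tolerance = 1e-12)
  expect_equal(row_ab$p, 1, tolerance = 1e-12)
})

test_that("compare_groups assembles summaries and gates the post hoc", {
  set.seed(9)
  x <- c(rnorm(5), rnorm(5), rnorm(5) + 30)
  g <- rep(c("g1", "g2", "g3"), each = 5)
  cg <- compare_groups(x, g)
  expect_identical(nrow(cg$summary), 3L)
  expect_true(is.na(cg$kw$p_exact))    # total n = 15: no exact enumeration
  if (cg$kw$p < 0.05) expect_s3_class(cg$dunn, "dunn_test")
})

test_that("chi-square p tracks the permutation distribution at n = 5 x 3", {
  # the study sample size: compare the chi-square p with a seeded
  # Monte-Carlo permutation p (the full enumeration is astronomically
  # large at n = 15); agreement within 0.05 absolute
  set.seed(18)
  g <- rep(c("a", "b", "c"), each = 5)
  for (i in 1:3) {
    x <- rnorm(15)
    kt <- kruskal_wallis(x, g)
    hs <- replicate(4000, h_oracle(x, sample(g)))
    p_mc <- mean(hs >= kt$h - 1e-12)
    expect_lt(abs(kt$p - p_mc), 0.05)
  }
})
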