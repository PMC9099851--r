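#' Median and interquartile range
#'
#' Linear-interpolation (type 7) quantiles, the convention used for all
#' median (Q1-Q3) summaries in the reports.
#'
#' @param values numeric vector (length >= 1)
#' @return named vector `median`, `q1`, `q3`
#' @export
median_iqr <- function(values) {
  if (length(values) == 0 || all(is.na(values)))
    stop("median_iqr: empty input")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), na.rm = TRUE,
                       names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

kw_h_statistic <- function(values, groups) {
  # tie-corrected Kruskal-Wallis H, computed from ranks
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  cf <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (cf <= 0) return(0)
  h / cf
}

#' Kruskal-Wallis one-way analysis of variance on ranks
#'
#' Tie-corrected H with a chi-square p-value (k - 1 degrees of freedom),
#' delegated to [stats::kruskal.test()]. For small samples (total n <= 12)
#' an exact permutation p-value is additionally computed by enumerating all
#' distinct assignments of the pooled observations to the group sizes.
#'
#' @param values numeric observations (pooled)
#' @param groups group labels, same length
#' @return object of class `kw_test`: `h`, `df`, `p` (chi-square),
#'   `p_exact` (NA when not computed), per-group `n`
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("kruskal_wallis: need at least 2 groups")
  if (length(values) < 3) stop("kruskal_wallis: need total n >= 3")
  if (length(unique(values)) == 1) {
    # all observations identical: no evidence of any difference
    out <- list(h = 0, df = nlevels(groups) - 1, p = 1, p_exact = 1,
                n = table(groups))
    class(out) <- "kw_test"
    return(out)
  }
  kt <- stats::kruskal.test(values, groups)
  p_exact <- NA_real_
  if (length(values) <= 12) {
    h_obs <- kw_h_statistic(values, groups)
    perms <- group_assignments(as.integer(table(groups)))
    hs <- vapply(perms, function(gi) kw_h_statistic(values, gi), numeric(1))
    p_exact <- mean(hs >= h_obs - 1e-12)
  }
  out <- list(h = unname(kt$statistic), df = unname(kt$parameter),
              p = kt$p.value, p_exact = p_exact, n = table(groups))
  class(out) <- "kw_test"
  out
}

# all distinct assignments of seq_len(sum(sizes)) positions to groups;
# returns a list of integer group-label vectors
group_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  recurse <- function(remaining, gi, labels) {
    if (length(remaining) == 0) {
      out[[length(out) + 1]] <<- labels
      return(invisible(NULL))
    }
    g <- length(sizes) - length(remaining) + 1
    k <- remaining[1]
    free <- which(labels == 0L)
    # fix the first free position into this group to avoid duplicates of
    # identical group-size blocks? sizes may differ; enumerate combinations
    cmb <- utils::combn(free, k)
    for (cc in seq_len(ncol(cmb))) {
      lab2 <- labels
      lab2[cmb[, cc]] <- g
      recurse(remaining[-1], gi, lab2)
    }
    invisible(NULL)
  }
  recurse(sizes, 1, integer(n))
  out
}

#' Dunn's post-hoc pairwise test
#'
#' Pairwise z statistics from pooled-rank means with the tie-corrected
#' variance, gated on a significant Kruskal-Wallis test: the test refuses
#' to run when `p_kw >= alpha`, mirroring the study protocol. Two-sided
#' p-values are reported unadjusted and Bonferroni-adjusted.
#'
#' @param values numeric observations (pooled)
#' @param groups group labels
#' @param p_kw the Kruskal-Wallis p-value obtained beforehand
#' @param alpha significance gate (default 0.05)
#' @return object of class `dunn_test`: data frame of pairs with `z`,
#'   `p`, `p_bonferroni`
#' @export
dunn_test <- function(values, groups, p_kw, alpha = 0.05) {
  if (!is.finite(p_kw)) stop("dunn_test: p_kw must be supplied")
  if (p_kw >= alpha)
    stop("dunn_test: omnibus test not significant (p = ", signif(p_kw, 3),
         " >= ", alpha, "); post-hoc comparisons are gated on a ",
         "significant Kruskal-Wallis test")
  groups <- factor(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tiecor) * (1 / ng[[a]] + 1 / ng[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    res$z[k] <- z
    res$p[k] <- 2 * stats::pnorm(-abs(z))
  }
  res$p_bonferroni <- pmin(1, res$p * ncol(pairs))
  structure(list(pairs = res, alpha = alpha, p_kw = p_kw),
            class = "dunn_test")
}

#' Group comparison: median (IQR), Kruskal-Wallis, gated Dunn post-hoc
#'
#' The full nonparametric layer applied to one metric: per-group median and
#' IQR, the omnibus Kruskal-Wallis test, and Dunn's pairwise test only when
#' the omnibus p is below `alpha`.
#'
#' @param values numeric observations
#' @param groups group labels
#' @param alpha significance level
#' @return object of class `group_stat`: `summary` data frame (one row per
#'   group), `kw`, and `dunn` (NULL when gated off)
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    mi <- median_iqr(values[groups == g])
    data.frame(group = g, n = sum(groups == g & !is.na(values)),
               median = mi["median"], q1 = mi["q1"], q3 = mi["q3"],
               row.names = NULL)
  }))
  kw <- kruskal_wallis(values, groups)
  dunn <- if (kw$p < alpha) dunn_test(values, groups, kw$p, alpha) else NULL
  structure(list(summary = summ, kw = kw, dunn = dunn, alpha = alpha),
            class = "group_stat")
}

#' @export
print.group_stat <- function(x, ...) {
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-8s %s\n", x$summary$group[i],
                fmt_median_iqr(x$summary$median[i], x$summary$q1[i],
                               x$summary$q3[i])))
  }
  cat(sprintf("  Kruskal-Wallis H = %.4g, p = %.4g", x$kw$h, x$kw$p))
  if (!is.na(x$kw$p_exact)) cat(sprintf(" (exact p = %.4g)", x$kw$p_exact))
  cat("\n")
  if (!is.null(x$dunn)) {
    for (i in seq_len(nrow(x$dunn$pairs))) {
      cat(sprintf("    Dunn %s vs %s: z = %.3f, p = %.4g\n",
                  x$dunn$pairs$group1[i], x$dunn$pairs$group2[i],
                  x$dunn$pairs$z[i], x$dunn$pairs$p[i]))
    }
  }
  invisible(x)
}

#' Format a value as "median (Q1-Q3)"
#' @param m,q1,q3 numeric scalars
#' @param digits decimal places
#' @return character scalar
#' @export
fmt_median_iqr <- function(m, q1, q3, digits = 2) {
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " (", fmt, "–", fmt, ")"), m, q1, q3)
}
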