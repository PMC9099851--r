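#' Study run configuration
#'
#'
#' Bundles everything one full in-silico study needs: the cohort, the mesh
#' profile for the per-sample CFD (desk profile: h_max 0.15 mm; full-run
#' profile: 0.1 mm), fluid and flow conditions, the high-shear threshold
#' and the region of interest.
#'
#' @param cohort a [cohort_config()]
#' @param mesh a [mesh_config()]; the desk default balances shear accuracy
#'   at strut surfaces (resolved at half a strut thickness) against cost
#' @param fluid a [fluid_properties()]
#' @param conds a [flow_conditions()]
#' @param solver a [solver_opts()]
#' @param params [bif_params()] of the simulated bifurcation; the cohort
#'   default truncates the unstented side branch at 10 mm and the proximal
#'   segment at 11.5 mm (the parabolic inlet needs no development length),
#'   trimming solver cost without touching the stented region
#' @param gamma_c high-shear threshold (1/s)
#' @param groups subset of strategy groups to run (default all)
#' @param do_cfd run the flow stage (disable for OCT/statistics-only runs)
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @return object of class `run_config`
#' @export
run_config <- function(cohort = cohort_config(),
                       mesh = mesh_config(h_max = 0.15,
                                          near_wall_factor = 0.5),
                       fluid = fluid_properties(),
                       conds = flow_conditions(),
                       solver = solver_opts(tol = 1e-5, picard_iters = 0,
                                            chord_rel = 0.5),
                       params = bif_params(len_prox = 11.5, len_mb = 15,
                                           len_sb = 10),
                       gamma_c = 1000, groups = NULL, do_cfd = TRUE,
                       out_dir = NULL) {
  structure(list(cohort = cohort, mesh = mesh, fluid = fluid,
                 conds = conds, solver = solver, params = params,
                 gamma_c = gamma_c, groups = groups, do_cfd = do_cfd,
                 out_dir = out_dir),
            class = "run_config")
}

# strut-free reference solutions are memoized per (geometry, mesh, flow)
# configuration: every cohort sample warm-starts from the same field
.base_cache <- new.env(parent = emptyenv())

base_solution <- function(geom, mesh_cfg, fluid, conds) {
  key <- rlang::hash(list(geom$params, mesh_cfg, fluid, conds))
  if (!is.null(.base_cache[[key]])) return(.base_cache[[key]])
  mesh0 <- generate_mesh(geom, NULL, mesh_cfg)
  f0 <- solve_steady_flow(mesh0, fluid, conds,
                          solver_opts(picard_iters = 2))
  .base_cache[[key]] <- list(mesh = mesh0, field = f0)
  .base_cache[[key]]
}

#' Interpolate a flow field onto another mesh (warm start)
#'
#' @param mesh_from mesh the field lives on
#' @param field the `flow_field`
#' @param mesh_to target mesh
#' @return list with nodal `u`, `v`, `p_kin` on `mesh_to` (zero outside
#'   `mesh_from`, e.g. inside strut obstacles)
#' @export
interp_flow <- function(mesh_from, field, mesh_to) {
  loc <- locate_points(mesh_from$nodes, mesh_from$tri, mesh_to$nodes)
  ok <- loc$tri > 0
  n <- nrow(mesh_to$nodes)
  init <- list(u = numeric(n), v = numeric(n), p_kin = numeric(n))
  if (any(ok)) {
    tv <- mesh_from$tri[loc$tri[ok], , drop = FALSE]
    w <- loc$bary[ok, , drop = FALSE]
    init$u[ok] <- rowSums(w * matrix(field$u[tv], ncol = 3))
    init$v[ok] <- rowSums(w * matrix(field$v[tv], ncol = 3))
    init$p_kin[ok] <- rowSums(w * matrix(field$p_kin[tv], ncol = 3))
  }
  init
}

#' Run the full in-silico study
#'
#' Generates the synthetic cohort, runs geometry, meshing, flow and shear
#' metrics for every sample (warm-starting each nonlinear solve from the
#' strut-free reference solution), computes the OCT metrics, and applies
#' the nonparametric statistics per metric. A sample whose flow solve
#' diverges is dropped with a warning; a group with no successful sample
#' aborts the study.
#'
#' @param cfg a [run_config()]
#' @return object of class `study_report`: per-sample `metrics` data
#'   frame, per-metric group statistics `stats`, and a provenance block
#' @export
run_study <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  geom <- build_bifurcation(cfg$params)
  if (!is.null(cfg$groups)) {
    keep <- intersect(cfg$groups, names(cfg$cohort$groups))
    if (length(keep) == 0) stop("run_study: no groups left")
    cfg$cohort$groups <- cfg$cohort$groups[keep]
  }
  cohort <- sample_cohort(cfg$cohort, geom)
  roi <- ostium_roi(geom)

  if (cfg$do_cfd)
    base <- base_solution(geom, cfg$mesh, cfg$fluid, cfg$conds)

  rows <- list()
  for (s in cohort$samples) {
    oct_cls <- classify_struts(s$pullback)
    ei <- elliptical_index(s$pullback,
                           stride = cfg$cohort$pullback$analysis_stride)
    thr <- thrombus_area_top3(s$pullback)
    prox <- proximal_summary(s$pullback)
    row <- data.frame(
      sample_id = s$sample_id, group = s$group,
      seed = cfg$cohort$seed,
      n_struts = oct_cls$total,
      pct_wa = oct_cls$pct_wa, pct_ma = oct_cls$pct_ma,
      pct_floating = oct_cls$pct_floating,
      ei = ei$ei, thrombus_area_mm2 = thr,
      d_min = prox$d_min, d_mean = prox$d_mean, d_max = prox$d_max,
      lumen_area_mm2 = prox$lumen_area_mm2,
      damage_cat1 = s$coating_damage[[1]],
      damage_cat2 = s$coating_damage[[2]],
      damage_cat3 = s$coating_damage[[3]],
      damage_cat4 = s$coating_damage[[4]],
      a_high_roi_mm2 = NA_real_, a_high_global_mm2 = NA_real_,
      shear_max = NA_real_, gamma_c = cfg$gamma_c,
      cfd_converged = NA, stringsAsFactors = FALSE)
    if (cfg$do_cfd) {
      res <- tryCatch({
        m <- generate_mesh(geom, s$layout, cfg$mesh)
        f <- solve_steady_flow(m, cfg$fluid, cfg$conds, cfg$solver,
                               init = interp_flow(base$mesh, base$field, m))
        sf <- compute_shear_rate_field(f, m)
        list(roi = compute_shear_metrics(sf, cfg$gamma_c, roi),
             glob = compute_shear_metrics(sf, cfg$gamma_c))
      }, error = function(e) {
        warning("run_study: sample ", s$sample_id, " dropped from CFD (",
                conditionMessage(e), ")", call. = FALSE)
        NULL
      })
      if (!is.null(res)) {
        row$a_high_roi_mm2 <- res$roi$a_high_mm2
        row$a_high_global_mm2 <- res$glob$a_high_mm2
        row$shear_max <- res$glob$shear_max
        row$cfd_converged <- TRUE
      } else {
        row$cfd_converged <- FALSE
      }
    }
    rows[[s$sample_id]] <- row
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  if (cfg$do_cfd) {
    okg <- tapply(metrics$cfd_converged, metrics$group, any)
    if (any(!okg))
      stop("run_study: no successful CFD sample in group(s) ",
           paste(names(okg)[!okg], collapse = ", "))
  }

  stat_cols <- c("pct_wa", "pct_ma", "pct_floating", "ei",
                 "thrombus_area_mm2", "d_min", "d_mean", "d_max",
                 "lumen_area_mm2", paste0("damage_cat", 1:4))
  if (cfg$do_cfd)
    stat_cols <- c(stat_cols, "a_high_roi_mm2", "a_high_global_mm2",
                   "shear_max")
  stats <- lapply(stats::setNames(stat_cols, stat_cols), function(cl)
    compare_groups(metrics[[cl]], metrics$group))

  report <- structure(
    list(metrics = metrics, stats = stats,
         provenance = list(seed = cfg$cohort$seed,
                           config_hash = rlang::hash(cfg),
                           package_version =
                             as.character(utils::packageVersion("stentflow")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "study_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

metric_digits <- function(metric) {
  if (grepl("^pct_", metric)) 1L
  else if (grepl("^damage", metric)) 0L
  else 2L
}

#' Render the study report as publication-style tables
#'
#' One row per metric with per-group "median (Q1-Q3)" columns and the
#' Kruskal-Wallis p-value; 2 decimals for mm/mm^2 metrics, 1 for
#' percentages, integers for counts.
#'
#' @param report a [run_study()] report
#' @return data frame of formatted cells
#' @export
render_tables <- function(report) {
  stopifnot(inherits(report, "study_report"))
  groups <- unique(report$metrics$group)
  out <- lapply(names(report$stats), function(metric) {
    gs <- report$stats[[metric]]
    dg <- metric_digits(metric)
    cells <- vapply(groups, function(g) {
      r <- gs$summary[gs$summary$group == g, ]
      if (nrow(r) == 0) return(NA_character_)
      fmt_median_iqr(r$median, r$q1, r$q3, digits = dg)
    }, character(1))
    c(metric = metric, cells,
      p_value = formatC(gs$kw$p, digits = 3, format = "g"))
  })
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("metric", groups, "p_value")
  df
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", nrow(x$metrics), "samples,",
      length(unique(x$metrics$group)), "groups; seed",
      x$provenance$seed, "\n")
  tb <- render_tables(x)
  print(tb, row.names = FALSE)
  invisible(x)
}
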