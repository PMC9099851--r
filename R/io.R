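#' Serialize a geometry (and optional layout) to JSON
#'
#' Vertex list, boundary tags, ostium segment and strut records; readable
#' by [read_layout_json()].
#'
#' @param geom a `bif_geometry`
#' @param layout optional `stent_layout`
#' @param file output path
#' @return the file path, invisibly
#' @export
write_geometry_json <- function(geom, layout = NULL, file) {
  obj <- list(
    vertices = unname(geom$vertices),
    edge_tags = geom$edge_tag,
    ostium = if (!is.null(geom$ostium))
      list(p1 = geom$ostium$p1, p2 = geom$ostium$p2,
           length = geom$ostium$length),
    params = geom$params[c("d_prox", "d_mb", "d_sb", "len_prox")])
  if (!is.null(layout))
    obj$layout <- list(strategy = layout$strategy, seed = layout$seed,
                       thickness_um = layout$spec$thickness_um,
                       struts = layout$struts)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Read strut records back from a geometry/layout JSON
#' @param file path written by [write_geometry_json()]
#' @return list with `vertices` and (if present) `struts` data frame
#' @export
read_layout_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  out <- list(vertices = as.matrix(obj$vertices))
  if (!is.null(obj$layout)) out$struts <- obj$layout$struts
  out
}

#' Lumen polygon as WKT
#' @param geom a `bif_geometry`
#' @return character scalar ("POLYGON ((x y, ...))")
#' @export
lumen_wkt <- function(geom) {
  v <- rbind(geom$vertices, geom$vertices[1, ])
  paste0("POLYGON ((",
         paste(sprintf("%.9g %.9g", v[, 1], v[, 2]), collapse = ", "),
         "))")
}

#' Write a mesh (with optional fields) as legacy ASCII VTK
#'
#' Unstructured-grid export viewable in ParaView; velocities are written
#' as point data, shear rate as cell data.
#'
#' @param mesh a `bif_mesh`
#' @param file output path
#' @param field optional `flow_field` (adds velocity/pressure point data)
#' @param shear optional `shear_field` (adds cell data)
#' @return the file path, invisibly
#' @export
write_vtk <- function(mesh, file, field = NULL, shear = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0",
               "stentflow unstructured mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(paste("CELLS", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1, mesh$tri[, 2] - 1,
                     mesh$tri[, 3] - 1), con)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(rep("5", m), con)
  if (!is.null(field)) {
    writeLines(c(paste("POINT_DATA", n),
                 "VECTORS velocity double"), con)
    writeLines(sprintf("%.9g %.9g 0", field$u, field$v), con)
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", field$p), con)
  }
  if (!is.null(shear)) {
    writeLines(c(paste("CELL_DATA", m),
                 "SCALARS shear_rate double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", shear$gamma), con)
  }
  invisible(file)
}

#' Write study-report artifacts to a directory
#'
#' `metrics.csv` (one row per sample), `stats.csv` (per-metric group
#' summaries and p-values), `tables.txt` (formatted median (IQR) tables)
#' and `provenance.json`.
#'
#' @param report a `study_report`
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  st <- do.call(rbind, lapply(names(report$stats), function(mt) {
    s <- report$stats[[mt]]
    data.frame(metric = mt, s$summary, h = s$kw$h, p = s$kw$p,
               p_exact = s$kw$p_exact, stringsAsFactors = FALSE)
  }))
  utils::write.csv(st, file.path(dir, "stats.csv"), row.names = FALSE)
  tb <- render_tables(report)
  writeLines(c(paste0("# seed ", report$provenance$seed,
                      "  config ", report$provenance$config_hash),
               utils::capture.output(print(tb, row.names = FALSE))),
             file.path(dir, "tables.txt"))
  jsonlite::write_json(report$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write per-frame pullback data as CSV
#' @param pb a `pullback_series`
#' @param file output path
#' @return the path, invisibly
#' @export
write_pullback_csv <- function(pb, file) {
  utils::write.csv(pb$frames, file, row.names = FALSE)
  invisible(file)
}

#' Read a structured key-value configuration file
#'
#' INI-style sections (`[geometry]`, `[stent]`, `[mesh]`, ...) of
#' `key = value` pairs; values are parsed as numbers where possible.
#'
#' @param file path to the configuration file
#' @return named list of sections, each a named list of values
#' @export
read_config <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); sect <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sect <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[sect]][[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Build geometry and strut parameters from a configuration file
#'
#' Applies the `[geometry]` section over [bif_params()] defaults and the
#' `[stent]` section over [strut_spec()] defaults.
#'
#' @param file path to a [read_config()] file
#' @return list with `params` and `spec`
#' @export
config_to_params <- function(file) {
  cfg <- read_config(file)
  p <- do.call(bif_params, modifyList(list(), cfg$geometry %||% list()))
  s <- do.call(strut_spec, modifyList(list(), cfg$stent %||% list()))
  list(params = p, spec = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a mesh in a minimal JSON dialect
#' @param mesh a `bif_mesh`
#' @param file path
#' @return the path (write) or a list with nodes/tri/boundary (read)
#' @export
write_mesh_json <- function(mesh, file) {
  jsonlite::write_json(list(nodes = unname(mesh$nodes),
                            triangles = unname(mesh$tri),
                            boundary = mesh$bedges),
                       file, digits = NA)
  invisible(file)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  list(nodes = as.matrix(obj$nodes), tri = as.matrix(obj$triangles),
       bedges = obj$boundary)
}

#' Group statistics from a long-format CSV
#'
#' Reads `(sample_id, group, metric, value)` rows and applies the
#' median/IQR + Kruskal-Wallis + gated-Dunn layer per metric.
#'
#' @param file CSV path
#' @param alpha significance level
#' @return named list of [compare_groups()] results, one per metric
#' @export
stats_from_csv <- function(file, alpha = 0.05) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "metric", "value")
  if (!all(need %in% names(d)))
    stop("stats_from_csv: need columns ", paste(need, collapse = ", "))
  lapply(split(d, d$metric), function(dd)
    compare_groups(dd$value, dd$group, alpha = alpha))
}
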