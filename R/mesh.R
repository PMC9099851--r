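#' Mesh configuration
#'
#' @param h_max maximum element edge length (mm)
#' @param near_wall_factor refinement ratio applied to element size along
#'   walls and strut surfaces (dimensionless, in (0, 1])
#' @param target_element_count_hint informational; the reference models used
#'   about 95,000 elements at `h_max = 0.1`
#' @return object of class `mesh_config`
#' @export
mesh_config <- function(h_max = 0.1, near_wall_factor = 0.25,
                        target_element_count_hint = 95000) {
  if (h_max <= 0) stop("mesh_config: h_max must be > 0")
  if (near_wall_factor <= 0 || near_wall_factor > 1)
    stop("mesh_config: near_wall_factor must be in (0, 1]")
  structure(list(h_max = h_max, near_wall_factor = near_wall_factor,
                 target_element_count_hint = target_element_count_hint),
            class = "mesh_config")
}

# Boundary loops of the fluid domain: the lumen polygon with well-apposed
# struts merged into the wall as square bumps, plus square holes for
# malapposed and floating struts.
fluid_boundary <- function(geom, layout = NULL) {
  verts <- geom$vertices
  nv <- nrow(verts)
  nxt <- c(2:nv, 1)
  flush <- NULL; freeq <- NULL; thick <- 0
  if (!is.null(layout)) {
    s <- layout$struts
    thick <- layout$spec$thickness_um / 1000
    flush <- s[s$apposition == "WA", , drop = FALSE]
    freeq <- s[s$apposition != "WA", , drop = FALSE]
  }
  half <- thick / 2
  pts <- list(); tags <- character(0)
  used_flush <- logical(if (is.null(flush)) 0 else nrow(flush))
  for (e in seq_len(nv)) {
    P <- verts[e, ]; Q <- verts[nxt[e], ]
    tg <- geom$edge_tag[e]
    L <- sqrt(sum((Q - P)^2))
    that <- (Q - P) / L
    inw <- rot90(that)     # fluid is left of P->Q
    pts[[length(pts) + 1]] <- P
    if (!is.null(flush) && nrow(flush) > 0 && tg == "wall") {
      tloc <- (flush$x - P[1]) * that[1] + (flush$y - P[2]) * that[2]
      dloc <- (flush$x - P[1]) * inw[1] + (flush$y - P[2]) * inw[2]
      on_edge <- abs(dloc - half) < 1e-6 & tloc > half & tloc < L - half
      ord <- order(tloc)
      for (k in ord[on_edge[ord]]) {
        used_flush[k] <- TRUE
        foot <- c(P[1] + tloc[k] * that[1], P[2] + tloc[k] * that[2])
        f1 <- foot - half * that; f2 <- foot + half * that
        r1 <- f1 + thick * inw; r2 <- f2 + thick * inw
        pts[[length(pts) + 1]] <- f1
        pts[[length(pts) + 1]] <- r1
        pts[[length(pts) + 1]] <- r2
        pts[[length(pts) + 1]] <- f2
        tags <- c(tags, tg, "strut", "strut", "strut")
      }
    }
    tags <- c(tags, tg)
  }
  if (!is.null(flush) && any(!used_flush))
    stop("fluid_boundary: flush strut(s) ",
         paste(flush$id[!used_flush], collapse = ", "),
         " could not be matched to a wall edge")
  outer <- list(pts = do.call(rbind, pts), tags = tags)
  holes <- list()
  if (!is.null(freeq) && nrow(freeq) > 0) {
    halfq <- thick / 2
    for (k in seq_len(nrow(freeq))) {
      sq <- strut_square(c(freeq$x[k], freeq$y[k]), halfq,
                         c(freeq$tx[k], freeq$ty[k]))
      holes[[length(holes) + 1]] <- list(pts = sq,
                                         tags = rep("strut", 4),
                                         strut_id = freeq$id[k])
    }
  }
  area <- polygon_area(outer$pts) -
    sum(vapply(holes, function(h) abs(polygon_area(h$pts)), numeric(1)))
  list(outer = outer, holes = holes, fluid_area = area, thick = thick)
}

# Subdivide every loop edge at the tag-dependent spacing; returns sampled
# points, subedges (index pairs into the sampled points) and subedge tags.
sample_loops <- function(bnd, cfg, gen_factor = 0.87) {
  h <- cfg$h_max; nwf <- cfg$near_wall_factor
  s_wall <- nwf * h
  s_strut <- if (bnd$thick > 0) min(nwf * h, bnd$thick / 2) else s_wall
  all_pts <- list(); edges <- list(); etags <- character(0)
  loops <- c(list(bnd$outer), bnd$holes)
  offset <- 0
  for (lp in loops) {
    v <- lp$pts; nvl <- nrow(v); nxt <- c(2:nvl, 1)
    idx_first <- offset + 1
    loc_pts <- list(); loc_n <- 0
    start_idx <- integer(nvl)
    for (e in seq_len(nvl)) {
      start_idx[e] <- offset + loc_n + 1
      loc_n <- loc_n + 1
      loc_pts[[loc_n]] <- v[e, ]
      P <- v[e, ]; Q <- v[nxt[e], ]
      L <- sqrt(sum((Q - P)^2))
      sp <- if (lp$tags[e] == "strut") s_strut else s_wall
      ns <- max(1L, ceiling(L / (gen_factor * sp)))
      if (ns > 1) {
        for (j in seq_len(ns - 1)) {
          loc_n <- loc_n + 1
          loc_pts[[loc_n]] <- P + (j / ns) * (Q - P)
        }
      }
    }
    # subedges: consecutive local points, wrapping to the loop start
    n_loc <- loc_n
    a <- offset + seq_len(n_loc)
    b <- c(offset + seq_len(n_loc)[-1], idx_first)
    # tag of each subedge = tag of the parent edge
    per_edge_counts <- diff(c(start_idx, offset + n_loc + 1))
    etags <- c(etags, rep(lp$tags, per_edge_counts))
    edges[[length(edges) + 1]] <- cbind(a, b)
    all_pts[[length(all_pts) + 1]] <- do.call(rbind, loc_pts)
    offset <- offset + n_loc
  }
  list(pts = do.call(rbind, all_pts),
       edges = do.call(rbind, edges),
       tags = etags,
       spacing = list(wall = s_wall, strut = s_strut))
}

hash01 <- function(a, b, c) {
  x <- sin(a * 12.9898 + b * 78.233 + c * 37.719) * 43758.5453
  x - floor(x)
}

# Graded interior point cloud: hierarchical hexagonal lattices accepted
# where the local target size falls in each level's band. Deterministic.
hex_grid <- function(xmin, xmax, ymin, ymax, g, ax, ay) {
  ry <- g * sqrt(3) / 2
  jj <- seq(floor((ymin - ay) / ry), ceiling((ymax - ay) / ry))
  pts <- lapply(jj, function(j) {
    off <- (j %% 2) * 0.5 * g
    ii <- seq(floor((xmin - ax - off) / g), ceiling((xmax - ax - off) / g))
    cbind(ax + off + ii * g, ay + j * ry)
  })
  do.call(rbind, pts)
}

interior_points <- function(geom, bnd, cfg, gen_factor = 0.87) {
  h <- cfg$h_max; nwf <- cfg$near_wall_factor
  thick <- bnd$thick
  s0 <- if (thick > 0) min(nwf * h, thick / 2) else nwf * h
  verts <- geom$vertices; nv <- nrow(verts); nxt <- c(2:nv, 1)
  E <- cbind(verts[, 1], verts[, 2], verts[nxt, 1], verts[nxt, 2])
  centers <- attr(bnd, "strut_centers")
  s_of <- function(p) {
    dw <- dist_to_segments(p, E)
    s <- pmin(h, nwf * h + 0.7 * dw)
    if (!is.null(centers) && nrow(centers) > 0) {
      dc <- rep(Inf, nrow(p))
      for (k in seq_len(nrow(centers)))
        dc <- pmin(dc, sqrt((p[, 1] - centers[k, 1])^2 +
                            (p[, 2] - centers[k, 2])^2))
      # element size holds at the strut-surface value over a plateau of
      # three strut thicknesses (the high-shear support), then grades out;
      # this keeps the thresholded area feature-resolved at every h_max
      s <- pmin(s, pmin(h, s0 + 0.8 * pmax(0, dc - 0.7 * thick - 3 * thick)))
      attr(s, "dc") <- dc
    }
    attr(s, "dw") <- dw
    s
  }
  g0 <- gen_factor * h
  n_lev <- max(0L, ceiling(log2(g0 / (gen_factor * s0))))
  y0 <- geom$frames$J[2]
  bb <- apply(bnd$outer$pts, 2, range)
  out <- list()
  for (lev in 0:n_lev) {
    g <- g0 / 2^lev
    g_hi <- if (lev == 0) Inf else g0 / 2^(lev - 1)
    cand <- NULL
    if (lev == 0) {
      cand <- hex_grid(bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], g, bb[1, 1], y0)
    } else {
      pieces <- list()
      # wall strips along each lumen edge
      d_lo <- max(0.55 * g, (g / gen_factor - nwf * h) / 0.7)
      d_hi <- (g_hi / gen_factor - nwf * h) / 0.7 + g
      if (d_hi > d_lo) {
        for (e in seq_len(nv)) {
          P <- verts[e, ]; Q <- verts[nxt[e], ]
          L <- sqrt(sum((Q - P)^2))
          that <- (Q - P) / L; inw <- rot90(that)
          loc <- hex_grid(g / 2, L - g / 2, d_lo, d_hi, g, 0, d_lo)
          if (!is.null(loc) && nrow(loc)) {
            keep <- loc[, 1] >= g / 2 & loc[, 1] <= L - g / 2 &
              loc[, 2] >= d_lo - 1e-12 & loc[, 2] <= d_hi
            loc <- loc[keep, , drop = FALSE]
            pieces[[length(pieces) + 1]] <- cbind(
              P[1] + loc[, 1] * that[1] + loc[, 2] * inw[1],
              P[2] + loc[, 1] * that[2] + loc[, 2] * inw[2])
          }
        }
      }
      # boxes around strut centers
      if (!is.null(centers) && nrow(centers) > 0) {
        r_hi <- 3.7 * thick + 1.25 * max(0, g_hi / gen_factor - s0) + g
        for (k in seq_len(nrow(centers))) {
          pieces[[length(pieces) + 1]] <- hex_grid(
            centers[k, 1] - r_hi, centers[k, 1] + r_hi,
            centers[k, 2] - r_hi, centers[k, 2] + r_hi, g,
            centers[k, 1], centers[k, 2])
        }
      }
      if (length(pieces)) cand <- do.call(rbind, pieces)
    }
    if (is.null(cand) || nrow(cand) == 0) next
    colnames(cand) <- NULL
    s <- s_of(cand)
    gx <- gen_factor * s
    ok <- gx >= g & gx < g_hi
    dw <- attr(s, "dw")
    ok <- ok & dw >= pmax(0.5 * g, 0.45 * gx)
    if (!is.null(attr(s, "dc"))) {
      clr <- attr(s, "dc") - 0.71 * thick
      ok <- ok & clr >= 0.5 * g
    }
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) next
    # inside the fluid region (outer polygon with bumps, minus holes)
    ins <- point_in_polygon(cand, bnd$outer$pts)
    for (hl in bnd$holes) ins <- ins & !point_in_polygon(cand, hl$pts)
    cand <- cand[ins, , drop = FALSE]
    if (nrow(cand) == 0) next
    # de-duplicate near-coincident candidates from overlapping source grids
    key <- paste(round(cand[, 1] / (0.6 * g)), round(cand[, 2] / (0.6 * g)))
    cand <- cand[!duplicated(key), , drop = FALSE]
    # deterministic jitter to break grid degeneracies
    j1 <- hash01(round(cand[, 1] / g * 7), round(cand[, 2] / g * 7), lev + 1)
    j2 <- hash01(round(cand[, 2] / g * 7), round(cand[, 1] / g * 7), lev + 31)
    cand[, 1] <- cand[, 1] + (j1 - 0.5) * 0.12 * g
    cand[, 2] <- cand[, 2] + (j2 - 0.5) * 0.12 * g
    out[[length(out) + 1]] <- cand
  }
  if (length(out)) do.call(rbind, out) else matrix(numeric(0), 0, 2)
}

#' Generate a boundary-refined triangular mesh of the fluid domain
#'
#' Discretizes the lumen (minus strut obstacles) with an unstructured
#' triangular mesh: constrained-conforming Delaunay triangulation of a
#' graded point cloud, flood-fill classification against the boundary
#' loops, and Laplacian smoothing. Elements along walls and strut surfaces
#' are refined by `near_wall_factor` (capped at half the strut thickness at
#' strut surfaces); element edges do not exceed `h_max`.
#'
#' @param geom a [build_bifurcation()] or [build_channel()] geometry
#' @param layout optional [place_struts()] layout; well-apposed struts are
#'   merged into the wall, malapposed and floating struts become holes
#' @param cfg a [mesh_config()]
#' @return object of class `bif_mesh`: `nodes` (mm), `tri` (element
#'   connectivity, counter-clockwise), `areas_mm2`, `bedges` (boundary
#'   edges with tags), node roles, and the generating configuration
#' @export
generate_mesh <- function(geom, layout = NULL, cfg = mesh_config()) {
  stopifnot(inherits(geom, "bif_geometry"), inherits(cfg, "mesh_config"))
  widths <- c(geom$params$d_prox, geom$params$d_mb, geom$params$d_sb)
  widths <- widths[!vapply(widths, is.null, logical(1))]
  if (cfg$h_max >= min(unlist(widths)) / 10 + 1e-12)
    stop("generate_mesh: h_max must be below one tenth of the narrowest ",
         "channel width")
  bnd <- fluid_boundary(geom, layout)
  if (!is.null(layout)) {
    attr(bnd, "strut_centers") <- as.matrix(layout$struts[, c("x", "y")])
    # degenerate sliver check: free strut too close to a wall without touching
    thick <- bnd$thick
    for (hl in bnd$holes) {
      segs <- cbind(hl$pts, hl$pts[c(2:4, 1), ])
      dmin <- min(dist_to_segments(matrix(geom$vertices, ncol = 2),
                                   segs))
      # distance of hole corners to lumen walls
      nv <- nrow(geom$vertices); nxt <- c(2:nv, 1)
      E <- cbind(geom$vertices[, 1], geom$vertices[, 2],
                 geom$vertices[nxt, 1], geom$vertices[nxt, 2])
      dcorner <- min(dist_to_segments(hl$pts, E))
      if (dcorner < cfg$h_max / 10 && dcorner > 1e-9)
        stop("generate_mesh: strut ", hl$strut_id, " leaves a degenerate ",
             "sliver (", signif(dcorner * 1000, 3), " um) between its ",
             "surface and the wall")
    }
  }
  smp <- sample_loops(bnd, cfg)
  ipts <- interior_points(geom, bnd, cfg)

  for (repair in 0:3) {
  pts <- rbind(smp$pts, ipts)
  n_fixed <- nrow(smp$pts)
  sub <- smp$edges
  subtags <- smp$tags

  for (pass in 1:10) {
    tri <- dt_triangulate(pts)
    np1 <- nrow(pts) + 1
    ek <- c(pmin(tri[, 1], tri[, 2]) * np1 + pmax(tri[, 1], tri[, 2]),
            pmin(tri[, 2], tri[, 3]) * np1 + pmax(tri[, 2], tri[, 3]),
            pmin(tri[, 1], tri[, 3]) * np1 + pmax(tri[, 1], tri[, 3]))
    want <- pmin(sub[, 1], sub[, 2]) * np1 + pmax(sub[, 1], sub[, 2])
    missing <- which(!(want %in% ek))
    if (length(missing) == 0) break
    if (pass == 10)
      stop("generate_mesh: could not recover ", length(missing),
           " constrained boundary edges")
    # split missing subedges at their midpoint (stays on the segment)
    newpts <- list(); newsub <- list(); newtags <- character(0)
    for (mi in missing) {
      a <- sub[mi, 1]; b <- sub[mi, 2]
      mid <- (pts[a, ] + pts[b, ]) / 2
      pts <- rbind(pts, mid)
      idm <- nrow(pts)
      newsub[[length(newsub) + 1]] <- rbind(c(a, idm), c(idm, b))
      newtags <- c(newtags, subtags[mi], subtags[mi])
    }
    sub <- rbind(sub[-missing, , drop = FALSE], do.call(rbind, newsub))
    subtags <- c(subtags[-missing], newtags)
    n_fixed <- nrow(pts) - nrow(ipts)
    # keep boundary points first so the fixed mask is an index threshold:
    # midpoints were appended at the end; rebuild ordering
    n_old_b <- nrow(pts) - nrow(ipts) - length(missing)
    reord <- c(seq_len(n_old_b),
               nrow(pts) - length(missing) + seq_along(missing),
               n_old_b + seq_len(nrow(ipts)))
    inv <- integer(nrow(pts)); inv[reord] <- seq_len(nrow(pts))
    pts <- pts[reord, , drop = FALSE]
    sub <- matrix(inv[sub], ncol = 2)
    n_fixed <- n_old_b + length(missing)
  }

  # flood fill from just inside the inlet
  inlet_sub <- which(subtags == "inlet")[1]
  a <- sub[inlet_sub, 1]; b <- sub[inlet_sub, 2]
  tvec <- pts[b, ] - pts[a, ]
  tvec <- tvec / sqrt(sum(tvec^2))
  seedp <- (pts[a, ] + pts[b, ]) / 2 + rot90(tvec) * smp$spacing$wall * 0.4
  keep <- dt_flood_keep(tri, pts, sub, seedp)
  tri <- tri[keep, , drop = FALSE]

  # drop unused nodes, renumber
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
  nodes <- pts[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)
  sub_kept <- sub[sub[, 1] %in% used & sub[, 2] %in% used, , drop = FALSE]
  subtags_kept <- subtags[sub[, 1] %in% used & sub[, 2] %in% used]
  sub2 <- matrix(remap[sub_kept], ncol = 2)
  fixed <- used <= n_fixed

  nodes <- dt_smooth(nodes, tri, fixed, 3L, 0.6)

  # repair pass: split any over-length edge at its midpoint and re-mesh
  ee <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  elen <- sqrt((nodes[ee[, 1], 1] - nodes[ee[, 2], 1])^2 +
               (nodes[ee[, 1], 2] - nodes[ee[, 2], 2])^2)
  if (max(elen) > cfg$h_max && repair < 3) {
    long <- unique(t(apply(ee[elen > cfg$h_max, , drop = FALSE], 1, sort)))
    mids <- (nodes[long[, 1], , drop = FALSE] +
             nodes[long[, 2], , drop = FALSE]) / 2
    ipts <- rbind(ipts, mids)
    next
  }
  break
  }

  # boundary edges of the kept mesh (edges on exactly one triangle),
  # oriented so the fluid lies on the left
  allee <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  np1 <- nrow(nodes) + 1
  kk <- pmin(allee[, 1], allee[, 2]) * np1 + pmax(allee[, 1], allee[, 2])
  single <- !(kk %in% kk[duplicated(kk)])
  bed <- allee[single, , drop = FALSE]
  subkey <- pmin(sub2[, 1], sub2[, 2]) * np1 + pmax(sub2[, 1], sub2[, 2])
  bkey <- pmin(bed[, 1], bed[, 2]) * np1 + pmax(bed[, 1], bed[, 2])
  mt <- match(bkey, subkey)
  if (anyNA(mt))
    stop("generate_mesh: untagged boundary edge after classification")
  bedges <- data.frame(n1 = bed[, 1], n2 = bed[, 2],
                       tag = subtags_kept[mt], stringsAsFactors = FALSE)

  # element areas and quality checks
  det2 <- (nodes[tri[, 2], 1] - nodes[tri[, 1], 1]) *
    (nodes[tri[, 3], 2] - nodes[tri[, 1], 2]) -
    (nodes[tri[, 3], 1] - nodes[tri[, 1], 1]) *
    (nodes[tri[, 2], 2] - nodes[tri[, 1], 2])
  if (any(det2 <= 0)) stop("generate_mesh: inverted element")
  areas <- det2 / 2
  rel <- abs(sum(areas) - bnd$fluid_area) / bnd$fluid_area
  if (rel > 1e-6)
    stop("generate_mesh: mesh area mismatch (relative error ",
         signif(rel, 3), ")")

  node_tag <- rep("interior", nrow(nodes))
  for (tg in c("outlet_mb", "outlet_sb", "inlet", "wall", "strut")) {
    sel <- bedges$tag == tg
    node_tag[unique(c(bedges$n1[sel], bedges$n2[sel]))] <- tg
  }
  structure(list(nodes = nodes, tri = tri, areas_mm2 = areas,
                 bedges = bedges, node_tag = node_tag,
                 fluid_area_mm2 = bnd$fluid_area, cfg = cfg,
                 geom = geom, layout = layout),
            class = "bif_mesh")
}

#' @export
print.bif_mesh <- function(x, ...) {
  cat("bif_mesh:", nrow(x$nodes), "nodes,", nrow(x$tri), "elements,",
      "area", signif(x$fluid_area_mm2, 6), "mm^2, h_max", x$cfg$h_max,
      "mm\n")
  invisible(x)
}

#' Maximum element edge length of a mesh (mm)
#' @param mesh a `bif_mesh`
#' @return numeric scalar
#' @export
max_edge_length <- function(mesh) {
  ee <- rbind(mesh$tri[, c(1, 2)], mesh$tri[, c(2, 3)], mesh$tri[, c(3, 1)])
  sqrt(max((mesh$nodes[ee[, 1], 1] - mesh$nodes[ee[, 2], 1])^2 +
           (mesh$nodes[ee[, 1], 2] - mesh$nodes[ee[, 2], 2])^2))
}
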