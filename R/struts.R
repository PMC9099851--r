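#' Strut cross-section specification
#'
#' Geometric description of a stent's strut cross-sections as seen in the
#' longitudinal plane: square obstacles of side equal to the strut
#' thickness. Conventional DES struts are 81 um thick; the
#' bifurcation-dedicated platform is 70 um with a two-strut connector zone
#' of 2.0-2.4 mm at the SB ostium and a proximal/distal diameter ratio of
#' 1.15-1.3.
#'
#' @param thickness_um strut thickness (micrometres)
#' @param ring_spacing_mm axial spacing between strut rings (mm)
#' @param connector_zone_mm length range of the ostial connector zone (mm),
#'   only used by the BD-DES strategy
#' @param prox_to_dist_ratio_range diameter step ratio of the dedicated
#'   platform (dimensionless, informational)
#' @return object of class `strut_spec`
#' @export
strut_spec <- function(thickness_um = 81, ring_spacing_mm = 1.0,
                       connector_zone_mm = c(2.0, 2.4),
                       prox_to_dist_ratio_range = c(1.15, 1.3)) {
  if (thickness_um <= 0) stop("strut_spec: thickness must be > 0")
  if (ring_spacing_mm * 1000 <= thickness_um)
    stop("strut_spec: ring spacing must exceed the strut thickness")
  structure(list(thickness_um = thickness_um,
                 ring_spacing_mm = ring_spacing_mm,
                 connector_zone_mm = connector_zone_mm,
                 prox_to_dist_ratio_range = prox_to_dist_ratio_range),
            class = "strut_spec")
}

#' Default strut spec for a stenting strategy
#' @param strategy one of "KIO", "KBI", "BD-DES"
#' @return a [strut_spec()]
#' @export
default_strut_spec <- function(strategy) {
  if (strategy == "BD-DES") strut_spec(thickness_um = 70) else strut_spec(81)
}

#' Largest-remainder apportionment of counts to fractions
#' @param n total count
#' @param fractions non-negative fractions summing to 1
#' @return integer vector summing to `n`
#' @export
largest_remainder <- function(n, fractions) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("largest_remainder: fractions must be in [0,1] and sum to 1")
  raw <- n * fractions
  base <- floor(raw)
  rem <- raw - base
  k <- n - sum(base)
  if (k > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(k)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

strut_square <- function(center, half, tangent) {
  nrm <- rot90(tangent)
  rbind(center - half * tangent - half * nrm,
        center + half * tangent - half * nrm,
        center + half * tangent + half * nrm,
        center - half * tangent + half * nrm)
}

#' Place strut obstacles for a stenting strategy
#'
#' Distributes square strut cross-sections over the stented walls and the SB
#' ostium so that the realized apposition-state mix (well-apposed WA,
#' malapposed MA, floating) equals the requested fractions up to
#' largest-remainder rounding. Well-apposed struts sit flush on the wall
#' (wall gap 0); malapposed struts stand off the wall by a gap drawn
#' uniformly from (1, 2] strut thicknesses; floating struts sit on the
#' ostium cross-section. The BD-DES strategy places exactly two dedicated
#' connector struts in the ostial connector zone: they cross the ostium only
#' if the mix allocates floating struts (at most two), otherwise they attach
#' well-apposed at the two ends of the zone.
#'
#' @param geom a [build_bifurcation()] geometry
#' @param strategy "KIO", "KBI" or "BD-DES"
#' @param spec a [strut_spec()]; defaults per strategy
#' @param mix apposition fractions `c(WA, MA, floating)`, summing to 1
#' @param seed integer seed; the layout is a pure function of its arguments
#' @param n_struts total number of strut cross-sections in the analyzed
#'   region (calibration parameter; the device count per frame is not
#'   printed, only the Table 1 percentages constrain it)
#' @param prox_cover,mb_cover stented wall coverage upstream (proximal
#'   segment) and downstream (MB) of the junction (mm)
#' @return object of class `stent_layout`: data frame `struts` with one row
#'   per strut (center, side, orientation, wall gap, apposition state) plus
#'   the generating arguments
#' @export
place_struts <- function(geom, strategy = c("KIO", "KBI", "BD-DES"),
                         spec = NULL, mix, seed = 1L, n_struts = 40L,
                         prox_cover = 9, mb_cover = 14) {
  strategy <- match.arg(strategy)
  if (is.null(spec)) spec <- default_strut_spec(strategy)
  stopifnot(inherits(geom, "bif_geometry"), inherits(spec, "strut_spec"))
  if (is.null(geom$ostium)) stop("place_struts: geometry has no ostium")
  if (length(mix) != 3 || any(mix < 0) || any(mix > 1) ||
      abs(sum(mix) - 1) > 1e-8)
    stop("place_struts: mix must be three fractions in [0,1] summing to 1")
  counts <- largest_remainder(n_struts, mix)
  names(counts) <- c("WA", "MA", "FLOATING")
  thick <- spec$thickness_um / 1000   # mm
  half <- thick / 2

  with_seed(seed, {
    rows <- list()
    n_float <- counts[["FLOATING"]]
    ost <- geom$ostium
    margin <- 2 * thick

    if (strategy == "BD-DES") {
      if (n_float > 2)
        stop("place_struts: BD-DES carries only two ostial connector struts; ",
             "a floating count > 2 is infeasible for this platform")
      zone <- stats::runif(1, geom$params$d_sb * 0 + spec$connector_zone_mm[1],
                           spec$connector_zone_mm[2])
      zone <- min(zone, ost$length - 2 * margin)
      # connector anchor positions, centered on the ostium midpoint
      s_anchor <- ost$length / 2 + c(-zone / 2, zone / 2)
      n_attach <- 2 - n_float
      if (n_float > 0) {
        s_float <- ost$length / 2 +
          (seq_len(n_float) - (n_float + 1) / 2) * zone
        for (s in s_float) {
          rows[[length(rows) + 1]] <- data.frame(
            x = ost$p1[1] + s * ost$tangent[1],
            y = ost$p1[2] + s * ost$tangent[2],
            side = "ostium", tx = ost$tangent[1], ty = ost$tangent[2],
            wall_gap_um = NA_real_, apposition = "FLOATING",
            is_connector = TRUE)
        }
      }
      if (n_attach > 0) {
        # attached connectors: flush on the walls flanking the ostium ends
        anchors <- list(
          list(track = geom$tracks$prox_lower, s = margin),
          list(track = geom$tracks$mb_inner, s = margin))
        for (k in seq_len(n_attach)) {
          tr <- anchors[[k]]$track
          pt <- tr$origin + anchors[[k]]$s * tr$tangent
          ctr <- pt + half * tr$inward
          rows[[length(rows) + 1]] <- data.frame(
            x = ctr[1], y = ctr[2], side = "lower_wall",
            tx = tr$tangent[1], ty = tr$tangent[2],
            wall_gap_um = 0, apposition = "WA", is_connector = TRUE)
        }
      }
    } else if (n_float > 0) {
      if (n_float * 2 * thick > ost$length)
        stop("place_struts: ", n_float, " floating struts cannot fit the ",
             round(ost$length, 2), " mm ostium at this thickness")
      s_float <- (seq_len(n_float) - 0.5) / n_float * ost$length
      for (s in s_float) {
        rows[[length(rows) + 1]] <- data.frame(
          x = ost$p1[1] + s * ost$tangent[1],
          y = ost$p1[2] + s * ost$tangent[2],
          side = "ostium", tx = ost$tangent[1], ty = ost$tangent[2],
          wall_gap_um = NA_real_, apposition = "FLOATING",
          is_connector = FALSE)
      }
    }

    n_conn_wa <- sum(vapply(rows, function(r)
      r$apposition == "WA", logical(1)))
    n_wall_wa <- counts[["WA"]] - n_conn_wa
    n_wall_ma <- counts[["MA"]]
    n_wall <- n_wall_wa + n_wall_ma
    if (n_wall_wa < 0)
      stop("place_struts: mix infeasible (too few WA for connector struts)")

    # candidate wall positions at ring_spacing along the four stented tracks
    covers <- c(prox_lower = prox_cover, prox_upper = prox_cover,
                mb_inner = mb_cover, mb_outer = mb_cover)
    cand <- list()
    for (nm in names(geom$tracks)) {
      tr <- geom$tracks[[nm]]
      cov <- min(covers[[nm]], tr$length - margin)
      s_off <- if (strategy == "BD-DES" &&
                   nm %in% c("prox_lower", "mb_inner")) margin + 3 * thick
               else margin
      s <- seq(s_off, cov, by = spec$ring_spacing_mm)
      cand[[nm]] <- lapply(s, function(si) list(track = tr, s = si, name = nm))
    }
    # round-robin interleave so struts spread across all four walls
    ord <- list(); i <- 1
    while (any(lengths(cand) > 0)) {
      for (nm in names(cand)) {
        if (length(cand[[nm]]) > 0) {
          ord[[i]] <- cand[[nm]][[1]]
          cand[[nm]] <- cand[[nm]][-1]
          i <- i + 1
        }
      }
    }
    if (n_wall > length(ord))
      stop("place_struts: ", n_wall, " wall struts exceed the ",
           length(ord), " available ring positions; reduce n_struts or ",
           "extend coverage")
    chosen <- ord[seq_len(n_wall)]
    ma_idx <- if (n_wall_ma > 0) sample(n_wall, n_wall_ma) else integer(0)
    for (k in seq_along(chosen)) {
      tr <- chosen[[k]]$track
      pt <- tr$origin + chosen[[k]]$s * tr$tangent
      side <- if (tr$inward[2] >= 0 || identical(chosen[[k]]$name, "mb_inner"))
        "lower_wall" else "upper_wall"
      if (k %in% ma_idx) {
        gap <- stats::runif(1, 1, 2) * thick    # strictly > thickness
        gap <- min(gap, 2 * thick)
        ctr <- pt + (gap + half) * tr$inward
        rows[[length(rows) + 1]] <- data.frame(
          x = ctr[1], y = ctr[2], side = side,
          tx = tr$tangent[1], ty = tr$tangent[2],
          wall_gap_um = gap * 1000, apposition = "MA", is_connector = FALSE)
      } else {
        ctr <- pt + half * tr$inward
        rows[[length(rows) + 1]] <- data.frame(
          x = ctr[1], y = ctr[2], side = side,
          tx = tr$tangent[1], ty = tr$tangent[2],
          wall_gap_um = 0, apposition = "WA", is_connector = FALSE)
      }
    }

    struts <- do.call(rbind, rows)
    struts$id <- seq_len(nrow(struts))
    layout <- structure(
      list(strategy = strategy, struts = struts, spec = spec,
           mix = mix, counts = counts, seed = seed, n_struts = n_struts),
      class = "stent_layout")
    validate_layout(layout, geom)
    layout
  })
}

#' Corner coordinates of every strut square in a layout
#' @param layout a [place_struts()] layout
#' @return list of 4 x 2 corner matrices (counter-clockwise)
#' @export
strut_squares <- function(layout) {
  half <- layout$spec$thickness_um / 2000
  lapply(seq_len(nrow(layout$struts)), function(i) {
    r <- layout$struts[i, ]
    strut_square(c(r$x, r$y), half, c(r$tx, r$ty))
  })
}

validate_layout <- function(layout, geom) {
  s <- layout$struts
  thick <- layout$spec$thickness_um / 1000
  if (nrow(s) >= 2) {
    d <- as.matrix(stats::dist(s[, c("x", "y")]))
    diag(d) <- Inf
    if (min(d) < thick * sqrt(2) - 1e-9)
      stop("place_struts: strut squares overlap")
  }
  sq <- strut_squares(layout)
  for (k in seq_along(sq)) {
    ctr <- c(s$x[k], s$y[k])
    probe <- sq[[k]] + 1e-6 * (matrix(ctr, 4, 2, byrow = TRUE) - sq[[k]])
    if (!all(point_in_polygon(probe, geom$vertices)))
      stop("place_struts: strut ", k, " extends outside the lumen")
  }
  invisible(layout)
}

#' Re-derive apposition labels from geometry (the classification rule)
#'
#' Floating iff the strut sits on the ostium (no wall behind it); malapposed
#' iff its wall gap strictly exceeds the strut thickness; well-apposed
#' otherwise.
#'
#' @param side character vector (`ostium`, `lower_wall`, `upper_wall`)
#' @param wall_gap_um numeric wall gaps (micrometres; NA for ostium struts)
#' @param thickness_um strut thickness (micrometres)
#' @return character vector of apposition states
#' @export
apposition_rule <- function(side, wall_gap_um, thickness_um) {
  ifelse(side == "ostium", "FLOATING",
         ifelse(wall_gap_um > thickness_um, "MA", "WA"))
}
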