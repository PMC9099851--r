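#' Parameters of the 2D longitudinal bifurcation model
#'
#' Dimensions of the Y-shaped left-main bifurcation phantom: a proximal
#' segment that splits into the distal main branch (MB) and the side branch
#' (SB). Channel widths are the printed lumen diameters; the MB and SB axes
#' each make `angle_branch_prox` with the proximal axis, so the MB-SB angle
#' is `angle_mb_sb`. All lengths in mm, angles in degrees.
#'
#' @param d_prox proximal channel width (mm)
#' @param d_mb distal main-branch width (mm)
#' @param d_sb side-branch width (mm)
#' @param angle_mb_sb angle between MB and SB axes (degrees)
#' @param angle_branch_prox angle between each branch axis and the proximal
#'   axis (degrees); `angle_mb_sb` and `angle_branch_prox` must be consistent
#'   only in the symmetric case, otherwise the MB angle is
#'   `180 - angle_branch_prox` above the proximal axis and the SB angle is
#'   `angle_mb_sb - (180 - angle_branch_prox)` below it
#' @param len_prox,len_mb,len_sb segment lengths measured along each axis
#'   from the axis junction (mm)
#' @param ostium_width width of the SB ostium cross-section (mm); defaults
#'   to `d_sb`
#' @return object of class `bif_params`
#' @export
bif_params <- function(d_prox = 5.5, d_mb = 3.5, d_sb = 3.5,
                       angle_mb_sb = 90, angle_branch_prox = 135,
                       len_prox = 15, len_mb = 15, len_sb = 15,
                       ostium_width = d_sb) {
  p <- list(d_prox = d_prox, d_mb = d_mb, d_sb = d_sb,
            angle_mb_sb = angle_mb_sb, angle_branch_prox = angle_branch_prox,
            len_prox = len_prox, len_mb = len_mb, len_sb = len_sb,
            ostium_width = ostium_width)
  lens <- c(d_prox, d_mb, d_sb, len_prox, len_mb, len_sb, ostium_width)
  if (any(!is.finite(unlist(p)))) stop("bif_params: non-finite value")
  if (any(lens <= 0)) stop("bif_params: all lengths must be > 0")
  if (d_prox <= d_mb || d_prox <= d_sb)
    stop("bif_params: proximal diameter must exceed both branch diameters")
  if (angle_mb_sb <= 0 || angle_mb_sb >= 180)
    stop("bif_params: angle_mb_sb must lie in (0, 180)")
  th_mb <- 180 - angle_branch_prox
  th_sb <- angle_mb_sb - th_mb
  if (th_mb <= 0 || th_mb >= 90 || th_sb <= 0 || th_sb >= 90)
    stop("bif_params: branch angles give a degenerate (non-Y) geometry")
  p$theta_mb <- th_mb
  p$theta_sb <- th_sb
  class(p) <- "bif_params"
  p
}

deg2rad <- function(d) d * pi / 180

rot90 <- function(v) c(-v[2], v[1])

seg_intersect <- function(p1, d1, p2, d2) {
  # point on line p1 + t d1 equal to p2 + s d2; returns c(t, s)
  A <- cbind(d1, -d2)
  if (abs(det(A)) < 1e-12) stop("parallel wall lines cannot intersect")
  drop(solve(A, p2 - p1))
}

#' Build the 2D longitudinal bifurcation lumen
#'
#' Constructs the simple closed polygon of the lumen in the sagittal plane
#' (y up), with the carina at the origin, the proximal segment entering from
#' the left, the MB leaving upward and the SB opening from the lower wall.
#' Channel widths measured normal to each segment axis equal the requested
#' diameters exactly. Boundary edges are tagged `inlet`, `outlet_mb`,
#' `outlet_sb` or `wall`; the ostium segment spans the SB mouth
#' perpendicular to the SB axis, with length `ostium_width`.
#'
#' @param params a [bif_params()] object
#' @return object of class `bif_geometry` with elements `vertices`
#'   (counter-clockwise polygon, one row per vertex), `edge_role` and
#'   `edge_tag` (per polygon edge), `ostium` (endpoints, center, length),
#'   `tracks` (wall parametrizations used for strut placement), `frames`
#'   (axis origins and directions) and `params`
#' @export
build_bifurcation <- function(params = bif_params()) {
  stopifnot(inherits(params, "bif_params"))
  p <- params
  u_mb <- c(cos(deg2rad(p$theta_mb)), sin(deg2rad(p$theta_mb)))
  u_sb <- c(cos(deg2rad(p$theta_sb)), -sin(deg2rad(p$theta_sb)))
  n_mb <- rot90(u_mb)            # points up-left (outer side of MB)
  n_sb <- rot90(u_sb)            # points up toward MB (inner side of SB)

  # carina C = (0,0): intersection of MB inner wall and SB inner wall.
  # Solve t*u_mb - (d_mb/2)*n_mb = s*u_sb + (d_sb/2)*n_sb for (t, s),
  # then the axis junction J = (d_mb/2)*n_mb - t*u_mb.
  ts <- seg_intersect(-(p$d_mb / 2) * n_mb, u_mb, (p$d_sb / 2) * n_sb, u_sb)
  t_c <- ts[1]; s_c <- ts[2]
  if (t_c <= 0 || s_c <= 0)
    stop("build_bifurcation: branch walls do not form a carina wedge")
  J <- (p$d_mb / 2) * n_mb - t_c * u_mb
  C <- c(0, 0)

  y_lo <- J[2] - p$d_prox / 2
  y_up <- J[2] + p$d_prox / 2

  # A: proximal lower wall (y = y_lo) meets SB outer wall
  sb_out0 <- J - (p$d_sb / 2) * n_sb
  if (abs(u_sb[2]) < 1e-12) stop("build_bifurcation: SB parallel to proximal axis")
  s_a <- (y_lo - sb_out0[2]) / u_sb[2]
  A <- sb_out0 + s_a * u_sb
  # B: proximal upper wall (y = y_up) meets MB outer wall
  mb_out0 <- J + (p$d_mb / 2) * n_mb
  t_b <- (y_up - mb_out0[2]) / u_mb[2]
  B <- mb_out0 + t_b * u_mb
  if (s_a <= 0 || t_b <= 0)
    stop("build_bifurcation: branch angles produce a self-intersecting junction")
  if (s_a >= p$len_sb || t_b >= p$len_mb || t_c >= p$len_mb || s_c >= p$len_sb)
    stop("build_bifurcation: segment lengths too short for the junction")

  # outlet corners
  M_in <- J + p$len_mb * u_mb - (p$d_mb / 2) * n_mb
  M_out <- J + p$len_mb * u_mb + (p$d_mb / 2) * n_mb
  S_in <- J + p$len_sb * u_sb + (p$d_sb / 2) * n_sb
  S_out <- J + p$len_sb * u_sb - (p$d_sb / 2) * n_sb
  x_in <- J[1] - p$len_prox
  if (x_in >= min(A[1], B[1]))
    stop("build_bifurcation: proximal length too short for the junction")
  I_lo <- c(x_in, y_lo)
  I_up <- c(x_in, y_up)

  verts <- rbind(I_lo, A, S_out, S_in, C, M_in, M_out, B, I_up)
  rownames(verts) <- c("inlet_lower", "ostium_prox_corner", "sb_outlet_outer",
                       "sb_outlet_inner", "carina", "mb_outlet_inner",
                       "mb_outlet_outer", "prox_upper_corner", "inlet_upper")
  role <- c("prox_lower", "sb_outer", "outlet_sb", "sb_inner", "mb_inner",
            "outlet_mb", "mb_outer", "prox_upper", "inlet")
  tag <- c(prox_lower = "wall", sb_outer = "wall", outlet_sb = "outlet_sb",
           sb_inner = "wall", mb_inner = "wall", outlet_mb = "outlet_mb",
           mb_outer = "wall", prox_upper = "wall", inlet = "inlet")[role]

  if (polygon_area(verts) < 0)
    stop("build_bifurcation: polygon orientation error")
  if (!polygon_is_simple(verts))
    stop("build_bifurcation: angles produce a self-intersecting polygon")

  # ostium: perpendicular SB cross-section anchored at A (on the outer wall)
  O2 <- A + p$ostium_width * n_sb
  s_o2 <- sum((O2 - (J + (p$d_sb / 2) * n_sb)) * u_sb)
  if (p$ostium_width > p$d_sb + 1e-9 || s_o2 < s_c - 1e-9)
    stop("build_bifurcation: ostium segment does not span the SB mouth")
  ostium <- list(p1 = A, p2 = O2, center = (A + O2) / 2,
                 length = sqrt(sum((O2 - A)^2)), tangent = n_sb)

  # wall tracks for strut placement: origin, direction of travel, inward
  # normal, usable length. Proximal tracks run upstream from the junction
  # corners; MB tracks run downstream from the carina / corner B.
  tracks <- list(
    prox_lower = list(origin = A, tangent = c(-1, 0), inward = c(0, 1),
                      length = A[1] - x_in),
    prox_upper = list(origin = B, tangent = c(-1, 0), inward = c(0, -1),
                      length = B[1] - x_in),
    mb_inner = list(origin = C, tangent = u_mb, inward = n_mb,
                    length = p$len_mb - t_c),
    mb_outer = list(origin = B, tangent = u_mb, inward = -n_mb,
                    length = p$len_mb - t_b)
  )

  g <- list(vertices = verts, edge_role = role, edge_tag = unname(tag),
            ostium = ostium, tracks = tracks,
            frames = list(J = J, u_mb = u_mb, n_mb = n_mb,
                          u_sb = u_sb, n_sb = n_sb,
                          t_carina = t_c, s_carina = s_c,
                          s_ostium = s_a, t_b = t_b),
            params = p)
  class(g) <- "bif_geometry"
  g
}

#' Build a straight 2D channel (validation geometry)
#'
#' A rectangular channel used for the plane-Poiseuille solver benchmarks:
#' inlet on the left, outlet (tagged `outlet_mb`) on the right, no-slip
#' walls top and bottom. Centered on y = 0.
#'
#' @param width channel width (mm)
#' @param length channel length (mm)
#' @return a `bif_geometry` object without ostium or wall tracks
#' @export
build_channel <- function(width = 5.5, length = 15) {
  stopifnot(width > 0, length > 0)
  h <- width / 2
  verts <- rbind(c(0, -h), c(length, -h), c(length, h), c(0, h))
  rownames(verts) <- c("inlet_lower", "outlet_lower", "outlet_upper",
                       "inlet_upper")
  role <- c("lower_wall", "outlet_mb", "upper_wall", "inlet")
  tag <- c("wall", "outlet_mb", "wall", "inlet")
  g <- list(vertices = verts, edge_role = role, edge_tag = tag,
            ostium = NULL, tracks = NULL,
            frames = list(J = c(length, 0)),
            params = list(d_prox = width, len_prox = length))
  class(g) <- "bif_geometry"
  g
}

#' Shoelace signed area of a polygon (positive = counter-clockwise)
#' @param v matrix of vertices, one row per vertex, not closed
#' @return signed area in squared input units
#' @export
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a + 1 || (a == 1 && b == n)) next
      if (segments_cross(v[a, ], v[j[a], ], v[b, ], v[j[b], ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) -
                              (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2) && (o3 != o4) && all(c(o1, o2, o3, o4) != 0)
}

#' Test whether points lie inside a polygon (ray casting)
#' @param pts n x 2 matrix
#' @param poly polygon vertices, one row per vertex, not closed
#' @return logical vector
#' @export
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, nrow(pts))
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j[k], 1]; yj <- poly[j[k], 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & is.finite((xj - xi) / (yj - yi)))
  }
  inside
}

#' Mean inlet velocity from a volumetric flow rate
#'
#' Converts a pump flow rate through a circular lumen into the mean axial
#' velocity, `U = Q / (pi (D/2)^2)` in SI units. The study's 200 mL/min
#' through the 5.5 mm proximal lumen gives 0.14 m/s.
#'
#' @param q_ml_min volumetric flow rate (mL/min)
#' @param d_mm lumen diameter (mm)
#' @return mean velocity (m/s)
#' @export
inlet_velocity_from_flow <- function(q_ml_min, d_mm) {
  if (!is.finite(q_ml_min) || !is.finite(d_mm) || q_ml_min <= 0 || d_mm <= 0)
    stop("inlet_velocity_from_flow: flow rate and diameter must be positive")
  q_si <- q_ml_min * 1e-6 / 60
  a_si <- pi * (d_mm * 1e-3 / 2)^2
  q_si / a_si
}
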