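#' High-shear area and maximum shear rate
#'
#' Reduces a shear-rate field to the two scalar endpoints: the area (mm^2)
#' where the shear rate exceeds the threshold (default 1000 1/s, the upper
#' end of the physiological arterial range of 100-1000 1/s) and the maximum
#' element shear rate. Elements are counted by centroid membership in the
#' region of interest.
#'
#' @param shear a [compute_shear_rate_field()] result
#' @param gamma_c high-shear threshold (1/s)
#' @param roi `"whole-domain"`, or a polygon (matrix of vertices, mm), or a
#'   list `list(center = c(x, y), radius = r)` for a circular window
#' @return object of class `shear_metrics`: `a_high_mm2`, `shear_max`,
#'   `gamma_c`, `roi_area_mm2`
#' @export
compute_shear_metrics <- function(shear, gamma_c = 1000,
                                  roi = "whole-domain") {
  stopifnot(inherits(shear, "shear_field"))
  inroi <- rep(TRUE, length(shear$gamma))
  if (is.list(roi) && !is.null(roi$center)) {
    inroi <- (shear$cx - roi$center[1])^2 + (shear$cy - roi$center[2])^2 <=
      roi$radius^2
  } else if (is.matrix(roi)) {
    inroi <- point_in_polygon(cbind(shear$cx, shear$cy), roi)
  } else if (!identical(roi, "whole-domain")) {
    stop("compute_shear_metrics: unrecognized roi")
  }
  if (!any(inroi)) stop("compute_shear_metrics: empty region of interest")
  g <- shear$gamma[inroi]; a <- shear$area_mm2[inroi]
  structure(list(a_high_mm2 = sum(a[g > gamma_c]),
                 shear_max = max(g),
                 gamma_c = gamma_c,
                 roi_area_mm2 = sum(a)),
            class = "shear_metrics")
}

#' Default ostium-centered region of interest
#'
#' A circular window centered on the SB ostium midpoint with radius one SB
#' diameter, covering the ostial jail and one diameter into each branch --
#' the region where strut-induced flow disturbance concentrates.
#'
#' @param geom a [build_bifurcation()] geometry
#' @param radius_factor radius in units of the SB diameter
#' @return roi list consumable by [compute_shear_metrics()]
#' @export
ostium_roi <- function(geom, radius_factor = 1) {
  if (is.null(geom$ostium)) stop("ostium_roi: geometry has no ostium")
  list(center = geom$ostium$center,
       radius = radius_factor * geom$params$d_sb)
}

#' Plot the shear-rate field
#'
#' Element-centroid map of the shear-rate magnitude on a log color scale,
#' with the high-shear threshold highlighted. Requires ggplot2.
#'
#' @param shear a [compute_shear_rate_field()] result
#' @param gamma_c threshold used for the highlight contour (1/s)
#' @return a ggplot object
#' @export
plot_shear_field <- function(shear, gamma_c = 1000) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_shear_field requires ggplot2")
  d <- data.frame(x = shear$cx, y = shear$cy,
                  gamma = pmax(shear$gamma, 1e-3),
                  high = shear$gamma > gamma_c)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$gamma), size = 0.3) +
    ggplot2::geom_point(data = d[d$high, , drop = FALSE],
                        color = "red", size = 0.4) +
    ggplot2::scale_color_viridis_c(trans = "log10",
                                   name = "shear rate (1/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  subtitle = paste0("red: > ", gamma_c, " 1/s")) +
    ggplot2::theme_minimal()
}
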