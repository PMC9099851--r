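#' OCT pullback acquisition configuration
#'
#' The imaging protocol: pullback at 10 mm/s imaged at 100 frames/s gives a
#' 0.1 mm frame interval; 540 frames cover 54 mm; analysis is performed at
#' 1 mm intervals (every tenth frame); axial resolution 15 um.
#'
#' @param frame_interval_mm axial distance between frames (mm)
#' @param n_frames frames per pullback
#' @param analysis_stride analyze every `analysis_stride`-th frame
#' @param resolution_um axial resolution (um)
#' @return object of class `pullback_config`
#' @export
pullback_config <- function(frame_interval_mm = 0.1, n_frames = 540,
                            analysis_stride = 10, resolution_um = 15) {
  stopifnot(frame_interval_mm > 0, n_frames >= 1, analysis_stride >= 1)
  structure(list(frame_interval_mm = frame_interval_mm, n_frames = n_frames,
                 analysis_stride = analysis_stride,
                 resolution_um = resolution_um),
            class = "pullback_config")
}

#' Classify struts by apposition state
#'
#' Applies the classification rule to all strut records of a pullback:
#' struts in the SB opening are floating; struts protruding into the lumen
#' by strictly more than one strut thickness are malapposed (MA); the rest
#' are well-apposed (WA). Counts and percentages are over all struts in the
#' bifurcation-ostium region.
#'
#' @param frames a `pullback_series` (see [simulate_pullback()]) or a data
#'   frame of strut records with columns `wall_gap_um`, `in_ostium`,
#'   `thickness_um`
#' @return object of class `strut_classification`: counts `n_wa`, `n_ma`,
#'   `n_floating` and percentages
#' @export
classify_struts <- function(frames) {
  st <- if (inherits(frames, "pullback_series")) frames$struts else frames
  if (is.null(st) || nrow(st) == 0) {
    st <- data.frame(wall_gap_um = numeric(0), in_ostium = logical(0),
                     thickness_um = numeric(0))
  }
  state <- apposition_rule(ifelse(st$in_ostium, "ostium", "wall"),
                           st$wall_gap_um, st$thickness_um)
  n <- c(WA = sum(state == "WA"), MA = sum(state == "MA"),
         FLOATING = sum(state == "FLOATING"))
  tot <- sum(n)
  pct <- if (tot > 0) 100 * n / tot else c(WA = NA_real_, MA = NA_real_,
                                           FLOATING = NA_real_)
  structure(list(n_wa = unname(n["WA"]), n_ma = unname(n["MA"]),
                 n_floating = unname(n["FLOATING"]), total = tot,
                 pct_wa = unname(pct["WA"]), pct_ma = unname(pct["MA"]),
                 pct_floating = unname(pct["FLOATING"])),
            class = "strut_classification")
}

#' Elliptical index of the proximal segment
#'
#' The ratio of maximal to minimal lumen diameter, Dmax/Dmin, of each
#' analyzed OCT frame (default every tenth frame, i.e. 1 mm intervals),
#' averaged over the analyzed frames of the proximal segment. 1.0 means a
#' perfectly circular lumen. The alternative reading -- the global maximal
#' diameter over the global minimal diameter across analyzed frames -- is
#' available via `method = "global"`.
#'
#' @param frames a `pullback_series` or data frame with columns `dmax_mm`,
#'   `dmin_mm` (and optionally `proximal`)
#' @param stride analyze every `stride`-th frame (1 = all supplied frames)
#' @param method "per-frame" (mean of per-frame ratios, default) or
#'   "global" (max Dmax / min Dmin)
#' @return list with `ei` and the per-frame ratios
#' @export
elliptical_index <- function(frames, stride = 1,
                             method = c("per-frame", "global")) {
  method <- match.arg(method)
  fr <- if (inherits(frames, "pullback_series")) frames$frames else frames
  if (!is.null(fr$proximal)) fr <- fr[fr$proximal, , drop = FALSE]
  fr <- fr[seq(1, nrow(fr), by = stride), , drop = FALSE]
  if (nrow(fr) == 0) stop("elliptical_index: no analyzed frames")
  if (any(fr$dmin_mm <= 0)) stop("elliptical_index: Dmin must be > 0")
  if (any(fr$dmax_mm < fr$dmin_mm))
    stop("elliptical_index: Dmax < Dmin in a frame")
  ratios <- fr$dmax_mm / fr$dmin_mm
  ei <- if (method == "per-frame") mean(ratios)
        else max(fr$dmax_mm) / min(fr$dmin_mm)
  list(ei = ei, ratios = ratios, n_frames = nrow(fr))
}

#' Mean thrombus area of the three most affected frames
#'
#' Selects the three OCT frames with the most extensive thrombus area in
#' the bifurcation region and averages them. With fewer than three
#' bifurcation-region frames the available frames are averaged with a
#' warning.
#'
#' @param frames a `pullback_series` or data frame with `thrombus_area_mm2`
#'   and `in_bifurcation` columns
#' @return mean area (mm^2)
#' @export
thrombus_area_top3 <- function(frames) {
  fr <- if (inherits(frames, "pullback_series")) frames$frames else frames
  if (!is.null(fr$in_bifurcation)) fr <- fr[fr$in_bifurcation, , drop = FALSE]
  if (nrow(fr) == 0)
    stop("thrombus_area_top3: no bifurcation-region frames")
  a <- sort(fr$thrombus_area_mm2, decreasing = TRUE)
  if (length(a) < 3)
    warning("thrombus_area_top3: fewer than 3 bifurcation-region frames; ",
            "averaging ", length(a))
  mean(a[seq_len(min(3, length(a)))])
}

#' Proximal lumen summary
#'
#' Minimum, mean and maximum of the frame mean-diameters over proximal
#' frames, plus the mean lumen area.
#'
#' @param frames a `pullback_series` or data frame with `dmax_mm`,
#'   `dmin_mm`, `lumen_area_mm2` and optionally `proximal`
#' @return list `d_min`, `d_mean`, `d_max` (mm), `lumen_area_mm2`
#' @export
proximal_summary <- function(frames) {
  fr <- if (inherits(frames, "pullback_series")) frames$frames else frames
  if (!is.null(fr$proximal)) fr <- fr[fr$proximal, , drop = FALSE]
  if (nrow(fr) == 0) stop("proximal_summary: no proximal frames")
  dm <- (fr$dmax_mm + fr$dmin_mm) / 2
  list(d_min = min(dm), d_mean = mean(dm), d_max = max(dm),
       lumen_area_mm2 = mean(fr$lumen_area_mm2))
}
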