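# Retinotopic map quality metrics: tilt of the zero-phase line, local phase
# scatter, and cortical magnification factor.

# Pixels of the zero-level band and its total-least-squares line.
# Returns centroid (row, col), unit direction (drow, dcol) of the fitted
# line, and the band pixel coordinates. Coordinates in pixel units.
zero_line_fit <- function(map, roi, zero_frac = 0.02) {
  v <- map$visual_angle
  vv <- v[roi]
  if (length(vv) < 2) stop("ROI is empty or too small", call. = FALSE)
  if (min(vv) > 0 || max(vv) < 0)
    stop("zero-phase line absent: visual angle does not change sign in ROI",
         call. = FALSE)
  thr <- zero_frac * (max(vv) - min(vv))
  # on coarse grids the nominal band can fall between pixel centers; widen
  # it just enough to include the pixels nearest the zero level
  thr <- max(thr, min(abs(vv)) * (1 + 1e-9) + 1e-12)
  band <- roi & abs(v) <= thr
  idx <- which(band, arr.ind = TRUE)
  if (nrow(idx) < 2)
    stop("zero-phase line absent: too few zero-level pixels in ROI",
         call. = FALSE)
  ctr <- colMeans(idx)
  x <- sweep(idx, 2, ctr)
  # principal axis of the band = TLS line direction
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  dirv <- ev$vectors[, 1]
  list(centroid = ctr, direction = dirv / sqrt(sum(dirv^2)), band = idx)
}

#' Tilt of the zero-phase line
#'
#' Fits the zero-level line of the visual-angle field inside the ROI by a
#' total-least-squares (principal-axis) fit of the pixels whose angle lies
#' within `zero_frac` of the map's angle range around zero, and returns the
#' acute angle between that line and the reference axis of the map:
#' mediolateral (columns) for elevation maps, anteroposterior (rows) for
#' azimuth maps.
#'
#' @param map a `retinotopic_map`.
#' @param roi logical analysis mask; must contain a sign change of the
#'   visual angle (the zero line must cross it).
#' @param zero_frac half-width of the zero-level band as a fraction of the
#'   ROI's angle range.
#' @return tilt angle in degrees, in `[0, 90]`.
#' @export
compute_map_tilt <- function(map, roi, zero_frac = 0.02) {
  if (!inherits(map, "retinotopic_map"))
    stop("'map' must be a retinotopic_map", call. = FALSE)
  fit <- zero_line_fit(map, roi, zero_frac)
  dr <- fit$direction[1]  # row component (anteroposterior)
  dc <- fit$direction[2]  # column component (mediolateral)
  len <- sqrt(dr^2 + dc^2)
  if (identical(map$axis, "azimuth")) {
    rad2deg(acos(min(1, abs(dr) / len)))
  } else {
    rad2deg(acos(min(1, abs(dc) / len)))
  }
}

# integer offsets within Euclidean distance `radius` of the center pixel
scatter_footprint <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

#' Local phase scatter of a retinotopic map
#'
#' For each selected pixel, computes the deviation of its visual angle from
#' the mean over its neighborhood (all integer offsets within Euclidean
#' distance `radius`, center included; radius 2.9 gives the full 5 x 5
#' square, 25 pixels). Centers are the up-to-`max_pixels` highest-amplitude
#' ROI pixels whose full footprint lies inside the map; ranking ties are
#' broken by row-major pixel order. The scatter is the standard deviation of
#' the deviations — low scatter means a smooth, well-ordered map.
#'
#' @param map a `retinotopic_map`.
#' @param roi logical analysis mask (responsive, artifact-free region).
#' @param radius neighborhood radius in pixels.
#' @param max_pixels cap on the number of center pixels used.
#' @return list with `scatter_sd` (SD of deviations, visual degrees) and
#'   `n_pixels_used`.
#' @export
compute_phase_scatter <- function(map, roi, radius = 2.9, max_pixels = 20000) {
  if (!inherits(map, "retinotopic_map"))
    stop("'map' must be a retinotopic_map", call. = FALSE)
  v <- map$visual_angle
  fp <- scatter_footprint(radius)
  r <- max(abs(c(fp$dr, fp$dc)))
  nr <- nrow(v); nc <- ncol(v)
  cand <- which(roi, arr.ind = TRUE)
  if (nrow(cand) == 0) stop("ROI is empty", call. = FALSE)
  inside <- cand[, 1] > r & cand[, 1] <= nr - r &
    cand[, 2] > r & cand[, 2] <= nc - r
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("ROI smaller than one footprint: no center pixel has a complete neighborhood",
         call. = FALSE)
  amp <- map$amplitude[cand]
  rowmajor <- (cand[, 1] - 1) * nc + cand[, 2]
  ord <- order(-amp, rowmajor)
  sel <- cand[ord[seq_len(min(max_pixels, nrow(cand)))], , drop = FALSE]
  # neighborhood means via offset accumulation (vectorized over centers)
  acc <- numeric(nrow(sel))
  for (k in seq_len(nrow(fp)))
    acc <- acc + v[cbind(sel[, 1] + fp$dr[k], sel[, 2] + fp$dc[k])]
  dev <- v[sel] - acc / nrow(fp)
  list(scatter_sd = stats::sd(dev), n_pixels_used = nrow(sel))
}

#' Cortical magnification factor
#'
#' Measures visual degrees per millimeter of cortex along the steepest-ascent
#' direction of the visual-angle field: the line perpendicular to the fitted
#' zero-level line, through its centroid. The sub-pixel positions where the
#' field attains `-span_deg/2` and `+span_deg/2` are located by bilinear
#' interpolation along that line, their cortical separation is measured in
#' mm, and the magnification is `span_deg / separation`.
#'
#' @param map a `retinotopic_map` with a positive `pixel_size_mm`.
#' @param roi logical analysis mask; both half-span levels must be attained
#'   inside it.
#' @param span_deg total visual-angle span between the two probe levels
#'   (default 10, i.e. the -5 and +5 degree lines).
#' @param zero_frac zero-band half-width passed to the line fit.
#' @param step_px sampling step along the profile, pixels.
#' @return magnification factor in visual degrees per mm.
#' @export
compute_magnification <- function(map, roi, span_deg = 10, zero_frac = 0.02,
                                  step_px = 0.25) {
  if (!inherits(map, "retinotopic_map"))
    stop("'map' must be a retinotopic_map", call. = FALSE)
  if (!is.finite(map$pixel_size_mm) || map$pixel_size_mm <= 0)
    stop("map has no positive pixel_size_mm", call. = FALSE)
  v <- map$visual_angle
  if (max(v[roi]) - min(v[roi]) < 1e-12)
    stop("zero gradient: visual-angle field is flat in ROI", call. = FALSE)
  fit <- zero_line_fit(map, roi, zero_frac)
  nvec <- c(-fit$direction[2], fit$direction[1])   # perpendicular to zero line
  # orient toward increasing visual angle
  p0 <- fit$centroid
  probe <- bilinear(v, p0[1] + nvec[1], p0[2] + nvec[2]) -
    bilinear(v, p0[1] - nvec[1], p0[2] - nvec[2])
  if (is.na(probe) || probe == 0)
    stop("zero gradient: no angle change across the zero line", call. = FALSE)
  if (probe < 0) nvec <- -nvec
  smax <- sqrt(nrow(v)^2 + ncol(v)^2)
  s <- seq(-smax, smax, by = step_px)
  rr <- p0[1] + s * nvec[1]
  cc <- p0[2] + s * nvec[2]
  prof <- bilinear(v, rr, cc)
  # restrict to ROI (nearest-pixel membership)
  ri <- round(rr); ci <- round(cc)
  ok <- !is.na(prof) & ri >= 1 & ri <= nrow(v) & ci >= 1 & ci <= ncol(v)
  ok[ok] <- roi[cbind(ri[ok], ci[ok])]
  s <- s[ok]; prof <- prof[ok]
  cross_at <- function(level) {
    d <- prof - level
    i <- which(d[-length(d)] * d[-1] <= 0 & diff(s) <= 2 * step_px)
    if (length(i) == 0)
      stop(sprintf("level %+g deg not attained along the steepest-ascent line in ROI",
                   level), call. = FALSE)
    # crossing closest to the centroid
    i <- i[which.min(abs(s[i]))]
    if (d[i + 1] == d[i]) return(s[i])
    s[i] + (s[i + 1] - s[i]) * (0 - d[i]) / (d[i + 1] - d[i])
  }
  s_lo <- cross_at(-span_deg / 2)
  s_hi <- cross_at(+span_deg / 2)
  sep_mm <- abs(s_hi - s_lo) * map$pixel_size_mm
  if (sep_mm == 0) stop("zero gradient: degenerate level separation",
                        call. = FALSE)
  span_deg / sep_mm
}

#' All three map metrics for one retinotopic map
#'
#' @param map a `retinotopic_map`.
#' @param roi logical analysis mask.
#' @param radius,max_pixels scatter parameters (see
#'   [compute_phase_scatter()]).
#' @param span_deg magnification span (see [compute_magnification()]).
#' @param zero_frac zero-band half-width for the line fit.
#' @return object of class `map_metrics` with fields `tilt_deg`,
#'   `scatter_sd`, `magnification_deg_per_mm`, `n_pixels_used`, `axis`.
#' @export
map_metrics <- function(map, roi, radius = 2.9, max_pixels = 20000,
                        span_deg = 10, zero_frac = 0.02) {
  sc <- compute_phase_scatter(map, roi, radius = radius,
                              max_pixels = max_pixels)
  structure(list(
    tilt_deg = compute_map_tilt(map, roi, zero_frac = zero_frac),
    scatter_sd = sc$scatter_sd,
    magnification_deg_per_mm = compute_magnification(map, roi,
                                                     span_deg = span_deg,
                                                     zero_frac = zero_frac),
    n_pixels_used = sc$n_pixels_used,
    axis = map$axis
  ), class = "map_metrics")
}

#' @export
print.map_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "Retinotopic map metrics (%s axis)\n",
    "  map tilt:             %6.2f deg\n",
    "  phase scatter (SD):   %6.3f deg (n = %d pixels)\n",
    "  magnification factor: %6.2f deg/mm\n"),
    x$axis, x$tilt_deg, x$scatter_sd, x$n_pixels_used,
    x$magnification_deg_per_mm))
  invisible(x)
}

#' @export
coef.map_metrics <- function(object, ...) {
  c(tilt_deg = object$tilt_deg, scatter_sd = object$scatter_sd,
    magnification_deg_per_mm = object$magnification_deg_per_mm)
}

#' @export
as.data.frame.map_metrics <- function(x, ...) {
  data.frame(axis = x$axis, tilt_deg = x$tilt_deg, scatter_sd = x$scatter_sd,
             magnification_deg_per_mm = x$magnification_deg_per_mm,
             n_pixels_used = x$n_pixels_used)
}
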