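# Fourier retinotopy: per-pixel extraction of the response at the stimulus
# frequency and combination of opposite sweep directions into an absolute
# (delay-free) retinotopic map in visual degrees.
#
# Phase convention used throughout: phase-degrees on the principal interval
# (-180, 180]; wrapping is applied after the forward-reverse subtraction and
# before halving.

# reshape nrow x ncol x frames array to frames x (nrow*ncol) matrix
stack_to_mat <- function(stack) {
  d <- dim(stack)
  t(matrix(stack, nrow = d[1] * d[2], ncol = d[3]))
}

#' High-pass filter a frame stack by boxcar subtraction
#'
#' Subtracts from each pixel's time series its centered moving average over a
#' window of `window_cycles` stimulus cycles (the boxcar). Constant signals
#' and slow drift are removed while any sinusoid at the stimulus frequency is
#' untouched in the window interior, because the mean of a sinusoid over a
#' whole number of cycles is zero. Edge frames whose window is truncated are
#' set to `NA` and dropped by [extract_fundamental()] rather than padded.
#'
#' @param stack numeric array `rows x cols x frames`.
#' @param frame_rate_hz acquisition frame rate.
#' @param stim_freq_hz stimulus frequency.
#' @param window_cycles boxcar length in stimulus cycles (default 2).
#' @return array of the same dimension with edge frames `NA`; attribute
#'   `valid` holds the inclusive frame range where the full window applied.
#' @export
highpass_boxcar <- function(stack, frame_rate_hz, stim_freq_hz,
                            window_cycles = 2) {
  d <- dim(stack)
  if (length(d) != 3) stop("'stack' must be a rows x cols x frames array",
                           call. = FALSE)
  w <- window_cycles * frame_rate_hz / stim_freq_hz
  if (abs(w - round(w)) > 1e-9)
    stop("boxcar window (window_cycles * frame_rate_hz / stim_freq_hz) must be a whole number of frames",
         call. = FALSE)
  w <- as.integer(round(w))
  if (w > d[3])
    stop(sprintf("boxcar window (%d frames) is longer than the stack (%d frames)",
                 w, d[3]), call. = FALSE)
  m <- stack_to_mat(stack)
  avg <- stats::filter(m, rep(1 / w, w), sides = 2)
  res <- m - avg
  ok <- which(!is.na(res[, 1]))
  out <- array(t(res), dim = d)
  structure(out, valid = c(min(ok), max(ok)))
}

#' Extract the fundamental Fourier component at the stimulus frequency
#'
#' For each pixel, computes the single-frequency Fourier component of its time
#' series at `stim_freq_hz`, normalized so a noiseless trace
#' `A * cos(2*pi*f*t + phi)` yields amplitude `A` and phase `phi` (phase
#' referenced to the acquisition clock, t = 0 at the first frame of the
#' original stack). Frames marked `NA` by [highpass_boxcar()] are dropped and
#' the remaining run is trimmed to a whole number of stimulus cycles.
#'
#' @param stack numeric array `rows x cols x frames`, possibly with `NA` edge
#'   frames from filtering.
#' @param stim_freq_hz stimulus frequency; must fall on a Fourier bin of the
#'   analyzed segment, i.e. `stim_freq_hz * n / frame_rate_hz` integer.
#' @param frame_rate_hz acquisition frame rate.
#' @param direction optional direction label (`"fwd"` / `"rev"`) carried
#'   through to the result.
#' @param axis optional axis label (`"elevation"` / `"azimuth"`).
#' @param pixel_size_mm optional pixel size carried through.
#' @return object of class `complex_response_map`: matrices `cos`, `sin`,
#'   `amplitude`, `phase_deg` (principal interval (-180, 180]; exactly zero
#'   traces report phase 0), plus the labels and metadata.
#' @export
extract_fundamental <- function(stack, stim_freq_hz, frame_rate_hz,
                                direction = NA_character_,
                                axis = NA_character_,
                                pixel_size_mm = NA_real_) {
  d <- dim(stack)
  if (length(d) != 3) stop("'stack' must be a rows x cols x frames array",
                           call. = FALSE)
  m <- stack_to_mat(stack)
  ok <- which(stats::complete.cases(m))
  if (length(ok) == 0) stop("no complete frames in stack", call. = FALSE)
  # use the longest initial run of complete frames
  run <- ok[seq_len(which.max(c(diff(ok) != 1, TRUE)))]
  fpc <- frame_rate_hz / stim_freq_hz
  if (abs(fpc - round(fpc)) > 1e-9)
    stop("stim_freq_hz must be representable as a whole number of frames per cycle",
         call. = FALSE)
  fpc <- as.integer(round(fpc))
  n_cyc <- length(run) %/% fpc
  if (n_cyc < 1)
    stop("fewer than one whole stimulus cycle of usable frames", call. = FALSE)
  use <- run[seq_len(n_cyc * fpc)]
  n <- length(use)
  tt <- (use - 1) / frame_rate_hz          # absolute acquisition clock
  wt <- 2 * pi * stim_freq_hz * tt
  x <- m[use, , drop = FALSE]
  cosc <- (2 / n) * crossprod(x, cos(wt))[, 1]
  sinc <- -(2 / n) * crossprod(x, sin(wt))[, 1]
  amp <- sqrt(cosc^2 + sinc^2)
  ph <- rad2deg(atan2(sinc, cosc))
  ph[amp == 0] <- 0
  dim(cosc) <- dim(sinc) <- dim(amp) <- dim(ph) <- d[1:2]
  structure(list(cos = cosc, sin = sinc, amplitude = amp, phase_deg = ph,
                 direction = direction, axis = axis,
                 stim_freq_hz = stim_freq_hz, frame_rate_hz = frame_rate_hz,
                 pixel_size_mm = pixel_size_mm, n_frames_used = n),
            class = "complex_response_map")
}

#' @export
print.complex_response_map <- function(x, ...) {
  cat(sprintf(paste0(
    "Complex response map (%d x %d pixels)\n",
    "  direction %s, axis %s, %d frames used at %g Hz stimulus\n",
    "  amplitude range [%.3g, %.3g]\n"),
    nrow(x$amplitude), ncol(x$amplitude), x$direction, x$axis,
    x$n_frames_used, x$stim_freq_hz, min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

#' Subtract the constant bias estimated from a reference region
#'
#' Estimates the constant (stimulus-locked, spatially uniform) bias as the
#' mean cosine/sine vector over a reference region chosen away from the
#' visually evoked activity and free of vascular artifacts, and subtracts
#' that two-dimensional vector from every pixel. After the operation the
#' reference region's mean vector is exactly (0, 0).
#'
#' @param cmap a `complex_response_map`.
#' @param reference_roi non-empty logical pixel mask of the reference region.
#' @return a bias-corrected `complex_response_map`.
#' @export
remove_bias <- function(cmap, reference_roi) {
  if (!inherits(cmap, "complex_response_map"))
    stop("'cmap' must be a complex_response_map", call. = FALSE)
  if (!is.logical(reference_roi) ||
      !identical(dim(reference_roi), dim(cmap$cos)))
    stop("'reference_roi' must be a logical mask matching the map", call. = FALSE)
  if (!any(reference_roi))
    stop("reference region is empty", call. = FALSE)
  bc <- mean(cmap$cos[reference_roi])
  bs <- mean(cmap$sin[reference_roi])
  out <- cmap
  out$cos <- cmap$cos - bc
  out$sin <- cmap$sin - bs
  out$amplitude <- sqrt(out$cos^2 + out$sin^2)
  out$phase_deg <- rad2deg(atan2(out$sin, out$cos))
  out$phase_deg[out$amplitude == 0] <- 0
  out$bias_estimate <- c(cos = bc, sin = bs)
  out
}

#' Combine opposite sweep directions into an absolute retinotopic map
#'
#' Subtracts the reverse-direction phase from the forward-direction phase
#' pixel by pixel, so the hemodynamic delay (common to both directions)
#' cancels exactly; the wrapped difference is halved to restore the position
#' scale and divided by `angle_conversion_factor` to express it in visual
#' degrees. Amplitudes of the two directions are averaged.
#'
#' @param map_fwd,map_rev `complex_response_map`s of a forward/reverse pair
#'   on the same axis and grid.
#' @param angle_conversion_factor divisor from phase-degrees to visual
#'   degrees; 7.2 corresponds to a 50 degree sweep per cycle (360/50).
#' @return object of class `retinotopic_map`: matrices `visual_angle`
#'   (degrees) and `amplitude`, plus `axis`, `pixel_size_mm` and the
#'   conversion factor.
#' @export
combine_opposite <- function(map_fwd, map_rev, angle_conversion_factor = 7.2) {
  if (!inherits(map_fwd, "complex_response_map") ||
      !inherits(map_rev, "complex_response_map"))
    stop("inputs must be complex_response_maps", call. = FALSE)
  if (!identical(dim(map_fwd$phase_deg), dim(map_rev$phase_deg)))
    stop("forward and reverse maps differ in shape", call. = FALSE)
  if (!identical(map_fwd$axis, map_rev$axis))
    stop("forward and reverse maps are on different axes", call. = FALSE)
  if (identical(map_fwd$direction, map_rev$direction) &&
      !is.na(map_fwd$direction))
    stop("maps carry the same direction label; need a forward/reverse pair",
         call. = FALSE)
  phase <- wrap_degrees(map_fwd$phase_deg - map_rev$phase_deg) / 2
  structure(list(
    visual_angle = phase / angle_conversion_factor,
    amplitude = (map_fwd$amplitude + map_rev$amplitude) / 2,
    axis = map_fwd$axis,
    pixel_size_mm = map_fwd$pixel_size_mm,
    angle_conversion_factor = angle_conversion_factor
  ), class = "retinotopic_map")
}

#' Fit an absolute retinotopic map from an imaging session
#'
#' The central fitting routine: high-pass filters both direction stacks
#' (boxcar over `window_cycles` stimulus cycles), extracts the fundamental
#' Fourier component at the stimulus frequency, optionally removes the
#' constant bias estimated from a reference region, and combines the opposite
#' directions into an absolute retinotopic map in visual degrees.
#'
#' @param session an `imaging_session` (see [simulate_imaging_session()] or
#'   [read_imaging_session()]).
#' @param reference_roi optional logical mask for bias removal; `NULL` skips
#'   the bias step.
#' @param window_cycles boxcar length in stimulus cycles.
#' @param angle_conversion_factor phase-degrees per visual degree (default
#'   7.2).
#' @return a `retinotopic_map`.
#' @examples
#' gt <- imaging_ground_truth(tilt_deg = 30, magnification_deg_per_mm = 44.8)
#' ses <- simulate_imaging_session(gt, nrow = 32, ncol = 32, n_frames = 120,
#'                                 frame_rate_hz = 5, stim_freq_hz = 0.125)
#' map <- retinotopic_map(ses)
#' map
#' @export
retinotopic_map <- function(session, reference_roi = NULL, window_cycles = 2,
                            angle_conversion_factor =
                              360 / session$ground_truth$sweep_extent_deg) {
  if (!inherits(session, "imaging_session"))
    stop("'session' must be an imaging_session", call. = FALSE)
  if (is.null(angle_conversion_factor) || !is.finite(angle_conversion_factor))
    angle_conversion_factor <- 7.2
  one <- function(stack, dirlab) {
    f <- highpass_boxcar(stack, session$frame_rate_hz, session$stim_freq_hz,
                         window_cycles = window_cycles)
    cm <- extract_fundamental(f, session$stim_freq_hz, session$frame_rate_hz,
                              direction = dirlab,
                              axis = session$direction_axis,
                              pixel_size_mm = session$pixel_size_mm)
    if (!is.null(reference_roi)) cm <- remove_bias(cm, reference_roi)
    cm
  }
  combine_opposite(one(session$stack_fwd, "fwd"), one(session$stack_rev, "rev"),
                   angle_conversion_factor = angle_conversion_factor)
}

#' @export
print.retinotopic_map <- function(x, ...) {
  cat(sprintf(paste0(
    "Absolute retinotopic map (%s axis), %d x %d pixels\n",
    "  visual angle range [%.2f, %.2f] deg; pixel size %s mm\n",
    "  phase-to-angle conversion factor %g\n"),
    x$axis, nrow(x$visual_angle), ncol(x$visual_angle),
    min(x$visual_angle), max(x$visual_angle),
    format(x$pixel_size_mm), x$angle_conversion_factor))
  invisible(x)
}

#' Summarize a retinotopic map with its quality metrics
#'
#' @param object a `retinotopic_map`.
#' @param roi logical analysis mask; defaults to the upper amplitude quartile.
#' @param ... passed to [map_metrics()].
#' @return a `map_metrics` object.
#' @export
summary.retinotopic_map <- function(object, roi = NULL, ...) {
  if (is.null(roi))
    roi <- object$amplitude >= stats::quantile(object$amplitude, 0.75)
  map_metrics(object, roi, ...)
}

#' Render a retinotopic map with a cyclic HSV color scale
#'
#' @param x a `retinotopic_map`.
#' @param which `"angle"` (default) or `"amplitude"`.
#' @param ... further arguments to [graphics::image()].
#' @export
plot.retinotopic_map <- function(x, which = c("angle", "amplitude"), ...) {
  which <- match.arg(which)
  z <- if (which == "angle") x$visual_angle else x$amplitude
  cols <- if (which == "angle")
    grDevices::hsv(seq(0, 5 / 6, length.out = 64)) else grDevices::gray.colors(64)
  # transpose + reverse rows so row 1 (anterior) appears at the top
  graphics::image(t(z[rev(seq_len(nrow(z))), ]), col = cols, axes = FALSE,
                  main = sprintf("%s map (%s)", x$axis, which), ...)
  if (which == "angle") {
    rng <- range(z)
    graphics::mtext(sprintf("visual angle %.1f to %.1f deg", rng[1], rng[2]),
                    side = 1, line = 0.5, cex = 0.8)
  }
  invisible(x)
}
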