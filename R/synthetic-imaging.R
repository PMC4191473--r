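# Synthetic intrinsic-signal imaging sessions with known retinotopic ground
# truth. The generator is the test surface for the whole mapping pipeline:
# every analysis stage is validated by recovering the parameters written here.

#' Ground truth for a synthetic imaging session
#'
#' Describes the planar retinotopic position field and the acquisition
#' nuisances (hemodynamic delay, noise, slow drift, common-mode bias) that a
#' synthetic session is built from. The position field is a plane: the
#' zero-level (monitor-center) line makes `tilt_deg` with the reference axis
#' of the map (mediolateral for elevation maps, anteroposterior for azimuth
#' maps) and the gradient magnitude is `magnification_deg_per_mm`.
#'
#' One stimulus cycle sweeps `sweep_extent_deg` of visual field, so visual
#' angle maps to phase as `phase = angle * 360 / sweep_extent_deg`; the
#' default 50 degree sweep gives the conventional phase-to-angle divisor
#' 360 / 50 = 7.2.
#'
#' @param tilt_deg angle of the zero-phase line relative to the reference
#'   axis, degrees in `[0, 90)`.
#' @param magnification_deg_per_mm visual degrees represented per mm of
#'   cortex; must be positive.
#' @param delay_phase_deg hemodynamic delay common to both sweep directions,
#'   phase-degrees.
#' @param sweep_extent_deg visual-field extent of one stimulus cycle, degrees.
#' @param signal_amplitude reflectance modulation amplitude inside the ROI
#'   (arbitrary reflectance units).
#' @param noise_sd SD of i.i.d. Gaussian noise added per pixel and frame.
#' @param drift_amplitude amplitude scale of the per-pixel slow polynomial
#'   (quadratic) drift.
#' @param bias_amplitude amplitude of a spatially uniform oscillation at the
#'   stimulus frequency (the constant bias that reference-region subtraction
#'   removes); `bias_phase_deg` is its phase.
#' @param bias_phase_deg phase of the common-mode bias, phase-degrees.
#' @param roi_mask logical matrix of pixels carrying visual signal, or `NULL`
#'   to use a centered disk of radius 3/8 of the smaller map dimension.
#' @param vascular_stripe if `TRUE`, a high-amplitude artifact stripe outside
#'   the ROI is added (emulating a surface vessel).
#' @param seed RNG seed stored with the ground truth.
#' @return an object of class `imaging_ground_truth`.
#' @seealso [simulate_imaging_session()]
#' @export
imaging_ground_truth <- function(tilt_deg,
                                 magnification_deg_per_mm,
                                 delay_phase_deg = 40,
                                 sweep_extent_deg = 50,
                                 signal_amplitude = 1,
                                 noise_sd = 0,
                                 drift_amplitude = 0,
                                 bias_amplitude = 0,
                                 bias_phase_deg = 0,
                                 roi_mask = NULL,
                                 vascular_stripe = FALSE,
                                 seed = 1L) {
  stopifnot_scalar(tilt_deg, "tilt_deg")
  if (tilt_deg < 0 || tilt_deg >= 90)
    stop("'tilt_deg' must lie in [0, 90)", call. = FALSE)
  stopifnot_scalar(magnification_deg_per_mm, "magnification_deg_per_mm")
  if (magnification_deg_per_mm <= 0)
    stop("'magnification_deg_per_mm' must be positive", call. = FALSE)
  stopifnot_scalar(sweep_extent_deg, "sweep_extent_deg")
  if (sweep_extent_deg <= 0)
    stop("'sweep_extent_deg' must be positive", call. = FALSE)
  structure(list(
    tilt_deg = tilt_deg,
    magnification_deg_per_mm = magnification_deg_per_mm,
    delay_phase_deg = delay_phase_deg,
    sweep_extent_deg = sweep_extent_deg,
    signal_amplitude = signal_amplitude,
    noise_sd = noise_sd,
    drift_amplitude = drift_amplitude,
    bias_amplitude = bias_amplitude,
    bias_phase_deg = bias_phase_deg,
    roi_mask = roi_mask,
    vascular_stripe = isTRUE(vascular_stripe),
    seed = as.integer(seed)
  ), class = "imaging_ground_truth")
}

# Planar visual-angle field (degrees) over an nrow x ncol pixel grid.
# Image convention (used by all modules): row index = anteroposterior axis,
# column index = mediolateral axis, origin top-left, row-major.
# For elevation maps the reference axis is mediolateral (columns); for
# azimuth maps it is anteroposterior (rows). The zero line passes through the
# grid center.
position_field <- function(nrow, ncol, axis, tilt_deg, mag_deg_per_mm,
                           pixel_size_mm) {
  t <- deg2rad(tilt_deg)
  r0 <- (nrow + 1) / 2
  c0 <- (ncol + 1) / 2
  x <- (matrix(seq_len(ncol), nrow, ncol, byrow = TRUE) - c0) * pixel_size_mm
  y <- (matrix(seq_len(nrow), nrow, ncol) - r0) * pixel_size_mm
  if (axis == "elevation") {
    # tilt 0: zero line along the mediolateral (column) axis
    mag_deg_per_mm * (cos(t) * y - sin(t) * x)
  } else {
    # tilt 0: zero line along the anteroposterior (row) axis
    mag_deg_per_mm * (cos(t) * x - sin(t) * y)
  }
}

#' Simulate a periodic-stimulation imaging session
#'
#' Builds forward- and reverse-direction reflectance stacks for a drifting-bar
#' retinotopy experiment. Inside the ROI, pixel (r, c) oscillates at the
#' stimulus frequency with phase `delay + position_phase(r, c)` in the forward
#' stack and `delay - position_phase(r, c)` in the reverse stack, where the
#' position phase encodes a planar retinotopic field (see
#' [imaging_ground_truth()]). Outside the ROI only noise, drift and the
#' optional common-mode bias are present.
#'
#' The session always contains a whole number of stimulus cycles:
#' `n_frames * stim_freq_hz / frame_rate_hz` must be an integer of at least 2,
#' and the frames per cycle `frame_rate_hz / stim_freq_hz` must be an integer.
#'
#' @param gt an [imaging_ground_truth()] object.
#' @param nrow,ncol stack dimensions in pixels.
#' @param n_frames frames per stack.
#' @param frame_rate_hz acquisition frame rate.
#' @param stim_freq_hz stimulus drift frequency.
#' @param direction_axis `"elevation"` (vertically drifting bar) or
#'   `"azimuth"` (horizontally drifting bar).
#' @param pixel_size_mm cortical size of one pixel in mm.
#' @param baseline constant reflectance level added to every frame.
#' @return an object of class `imaging_session`: list with `stack_fwd`,
#'   `stack_rev` (arrays `nrow x ncol x n_frames`), acquisition metadata and
#'   the `ground_truth` used.
#' @examples
#' gt <- imaging_ground_truth(tilt_deg = 30, magnification_deg_per_mm = 44.8)
#' ses <- simulate_imaging_session(gt, nrow = 32, ncol = 32, n_frames = 80,
#'                                 frame_rate_hz = 5, stim_freq_hz = 0.125)
#' dim(ses$stack_fwd)
#' @export
simulate_imaging_session <- function(gt,
                                     nrow = 64, ncol = 64,
                                     n_frames = 480,
                                     frame_rate_hz = 10,
                                     stim_freq_hz = 0.125,
                                     direction_axis = c("elevation", "azimuth"),
                                     pixel_size_mm = 0.01,
                                     baseline = 0) {
  if (!inherits(gt, "imaging_ground_truth"))
    stop("'gt' must be an imaging_ground_truth object", call. = FALSE)
  direction_axis <- match.arg(direction_axis)
  n_cycles <- n_frames * stim_freq_hz / frame_rate_hz
  if (abs(n_cycles - round(n_cycles)) > 1e-9 || round(n_cycles) < 2)
    stop(sprintf(paste0(
      "session must contain a whole number (>= 2) of stimulus cycles: ",
      "n_frames * stim_freq_hz / frame_rate_hz = %g"), n_cycles),
      call. = FALSE)
  fpc <- frame_rate_hz / stim_freq_hz
  if (abs(fpc - round(fpc)) > 1e-9)
    stop("frame_rate_hz / stim_freq_hz (frames per cycle) must be an integer",
         call. = FALSE)
  if (pixel_size_mm <= 0) stop("'pixel_size_mm' must be positive", call. = FALSE)

  roi <- gt$roi_mask
  if (is.null(roi)) roi <- disk_mask(nrow, ncol, radius = min(nrow, ncol) * 3 / 8)
  if (!is.logical(roi) || !all(dim(roi) == c(nrow, ncol)))
    stop("'roi_mask' must be a logical nrow x ncol matrix", call. = FALSE)

  angle <- position_field(nrow, ncol, direction_axis, gt$tilt_deg,
                          gt$magnification_deg_per_mm, pixel_size_mm)
  pos_phase <- angle * 360 / gt$sweep_extent_deg     # phase-degrees
  npix <- nrow * ncol
  tt <- (seq_len(n_frames) - 1) / frame_rate_hz
  wt <- 2 * pi * stim_freq_hz * tt                   # radians, length n_frames
  amp <- ifelse(roi, gt$signal_amplitude, 0)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(gt$seed)

  make_stack <- function(sign_pos) {
    ph <- deg2rad(gt$delay_phase_deg + sign_pos * pos_phase)   # nrow x ncol
    # pixels x frames: amp * cos(wt + ph)
    m <- (as.vector(amp) * cos(outer(as.vector(ph), wt, `+`)))
    if (gt$bias_amplitude != 0)
      m <- m + rep(gt$bias_amplitude *
                     cos(wt + deg2rad(gt$bias_phase_deg)), each = npix)
    if (gt$drift_amplitude != 0) {
      tau <- 2 * tt / max(tt) - 1
      co <- matrix(stats::runif(3 * npix, -1, 1), npix, 3)
      m <- m + gt$drift_amplitude *
        (co[, 1] %o% tau + co[, 2] %o% tau^2 + co[, 3] %o% rep(1, n_frames))
    }
    if (gt$vascular_stripe) {
      stripe <- matrix(FALSE, nrow, ncol)
      stripe[, seq_len(max(1L, ncol %/% 16))] <- TRUE
      stripe <- stripe & !roi
      m[as.vector(stripe), ] <- m[as.vector(stripe), ] +
        10 * gt$signal_amplitude
    }
    if (gt$noise_sd > 0)
      m <- m + matrix(stats::rnorm(npix * n_frames, sd = gt$noise_sd),
                      npix, n_frames)
    array(m + baseline, dim = c(nrow, ncol, n_frames))
  }

  structure(list(
    stack_fwd = make_stack(+1),
    stack_rev = make_stack(-1),
    frame_rate_hz = frame_rate_hz,
    stim_freq_hz = stim_freq_hz,
    direction_axis = direction_axis,
    pixel_size_mm = pixel_size_mm,
    n_frames = n_frames,
    ground_truth = gt
  ), class = "imaging_session")
}

#' @export
print.imaging_session <- function(x, ...) {
  d <- dim(x$stack_fwd)
  cat(sprintf(paste0(
    "Synthetic imaging session (%s axis)\n",
    "  stacks: %d x %d pixels, %d frames (fwd + rev)\n",
    "  frame rate %g Hz, stimulus %g Hz (%g cycles)\n",
    "  pixel size %g mm; ground-truth tilt %.1f deg, %.1f deg/mm\n"),
    x$direction_axis, d[1], d[2], d[3], x$frame_rate_hz, x$stim_freq_hz,
    x$n_frames * x$stim_freq_hz / x$frame_rate_hz, x$pixel_size_mm,
    x$ground_truth$tilt_deg, x$ground_truth$magnification_deg_per_mm))
  invisible(x)
}

#' Ground-truth visual-angle field of a synthetic session
#'
#' Returns the planar visual-angle field (degrees) the generator embedded in
#' a session, for closed-loop comparisons with the recovered map.
#'
#' @param session an `imaging_session`.
#' @return numeric matrix of visual angles in degrees.
#' @export
session_true_angle <- function(session) {
  d <- dim(session$stack_fwd)
  position_field(d[1], d[2], session$direction_axis,
                 session$ground_truth$tilt_deg,
                 session$ground_truth$magnification_deg_per_mm,
                 session$pixel_size_mm)
}
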