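# File formats: imaging sessions as multi-page TIFF pairs with a YAML
# sidecar, epoch sets as CSV (time column + one column per trial, header row
# carrying condition labels), retinotopic maps as matrix CSVs plus a PNG
# render, metrics as JSON.

# TIFF float pages are stored in [0, 1]; stacks are affinely rescaled on
# write and restored on read using scale/offset recorded in the sidecar.

#' Write an imaging session to disk
#'
#' Writes one multi-page 32-bit TIFF per sweep direction
#' (`<name>_fwd.tif`, `<name>_rev.tif`), the ROI mask as a single-page TIFF
#' (`<name>_roi.tif`), and a YAML sidecar (`<name>_meta.yaml`) holding the
#' acquisition metadata, the intensity scale/offset, and the full ground
#' truth block, so a session round-trips through the file pair.
#'
#' @param session an `imaging_session`.
#' @param dir output directory (created if needed).
#' @param name basename for the file set.
#' @return invisibly, the sidecar path.
#' @export
write_imaging_session <- function(session, dir, name = "session") {
  if (!inherits(session, "imaging_session"))
    stop("'session' must be an imaging_session", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  both <- c(session$stack_fwd, session$stack_rev)
  off <- min(both); sc <- max(both) - off
  if (sc == 0) sc <- 1
  pages <- function(stack) {
    d <- dim(stack)
    lapply(seq_len(d[3]), function(i) (stack[, , i] - off) / sc)
  }
  tiff::writeTIFF(pages(session$stack_fwd),
                  file.path(dir, paste0(name, "_fwd.tif")),
                  bits.per.sample = 32L)
  tiff::writeTIFF(pages(session$stack_rev),
                  file.path(dir, paste0(name, "_rev.tif")),
                  bits.per.sample = 32L)
  gt <- session$ground_truth
  roi <- gt$roi_mask
  if (is.null(roi)) {
    d <- dim(session$stack_fwd)
    roi <- disk_mask(d[1], d[2], radius = min(d[1], d[2]) * 3 / 8)
  }
  tiff::writeTIFF(roi * 1, file.path(dir, paste0(name, "_roi.tif")),
                  bits.per.sample = 8L)
  meta <- list(
    frame_rate_hz = session$frame_rate_hz,
    stim_freq_hz = session$stim_freq_hz,
    direction_axis = session$direction_axis,
    pixel_size_mm = session$pixel_size_mm,
    n_frames = session$n_frames,
    intensity_offset = off,
    intensity_scale = sc,
    ground_truth = list(
      tilt_deg = gt$tilt_deg,
      magnification_deg_per_mm = gt$magnification_deg_per_mm,
      delay_phase_deg = gt$delay_phase_deg,
      sweep_extent_deg = gt$sweep_extent_deg,
      signal_amplitude = gt$signal_amplitude,
      noise_sd = gt$noise_sd,
      drift_amplitude = gt$drift_amplitude,
      bias_amplitude = gt$bias_amplitude,
      bias_phase_deg = gt$bias_phase_deg,
      vascular_stripe = gt$vascular_stripe,
      seed = gt$seed
    )
  )
  side <- file.path(dir, paste0(name, "_meta.yaml"))
  yaml::write_yaml(meta, side)
  invisible(side)
}

#' Read an imaging session written by [write_imaging_session()]
#'
#' @param dir directory holding the file set.
#' @param name basename used at write time.
#' @return an `imaging_session`; the ground truth (including the ROI mask)
#'   is restored from the sidecar and the ROI TIFF.
#' @export
read_imaging_session <- function(dir, name = "session") {
  side <- file.path(dir, paste0(name, "_meta.yaml"))
  for (f in c(side, file.path(dir, paste0(name, c("_fwd.tif", "_rev.tif",
                                                  "_roi.tif")))))
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
  meta <- yaml::read_yaml(side)
  load_stack <- function(path) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e)
                        stop("cannot read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    arr * meta$intensity_scale + meta$intensity_offset
  }
  fwd <- load_stack(file.path(dir, paste0(name, "_fwd.tif")))
  rev <- load_stack(file.path(dir, paste0(name, "_rev.tif")))
  roi <- tiff::readTIFF(file.path(dir, paste0(name, "_roi.tif"))) > 0.5
  g <- meta$ground_truth
  gt <- imaging_ground_truth(
    tilt_deg = g$tilt_deg,
    magnification_deg_per_mm = g$magnification_deg_per_mm,
    delay_phase_deg = g$delay_phase_deg,
    sweep_extent_deg = g$sweep_extent_deg,
    signal_amplitude = g$signal_amplitude,
    noise_sd = g$noise_sd,
    drift_amplitude = g$drift_amplitude,
    bias_amplitude = g$bias_amplitude,
    bias_phase_deg = g$bias_phase_deg,
    roi_mask = roi,
    vascular_stripe = g$vascular_stripe,
    seed = g$seed
  )
  structure(list(
    stack_fwd = fwd, stack_rev = rev,
    frame_rate_hz = meta$frame_rate_hz,
    stim_freq_hz = meta$stim_freq_hz,
    direction_axis = meta$direction_axis,
    pixel_size_mm = meta$pixel_size_mm,
    n_frames = meta$n_frames,
    ground_truth = gt
  ), class = "imaging_session")
}

#' Write an epoch set as CSV
#'
#' First column is time in seconds; each remaining column is one trial and
#' its header is the trial's condition label.
#'
#' @param epochs an `epoch_set`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_epoch_set <- function(epochs, path) {
  if (!inherits(epochs, "epoch_set"))
    stop("'epochs' must be an epoch_set", call. = FALSE)
  m <- cbind(epochs$time, t(epochs$trials))
  colnames(m) <- c("time", epochs$condition)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param path CSV path.
#' @return an `epoch_set`.
#' @export
read_epoch_set <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2 || names(d)[1] != "time")
    stop("epoch CSV must have a 'time' column followed by trial columns",
         call. = FALSE)
  structure(list(
    time = d[[1]],
    trials = t(as.matrix(d[, -1, drop = FALSE])),
    condition = names(d)[-1]
  ), class = "epoch_set")
}

#' Write a retinotopic map as matrix files plus a PNG render
#'
#' Writes `<name>_angle.csv` (visual angle, degrees), `<name>_amplitude.csv`,
#' a metadata YAML, and a PNG render with a cyclic HSV color scale.
#'
#' @param map a `retinotopic_map`.
#' @param dir output directory.
#' @param name basename.
#' @param png also write the PNG render.
#' @return invisibly, the directory.
#' @export
write_retinotopic_map <- function(map, dir, name = "map", png = TRUE) {
  if (!inherits(map, "retinotopic_map"))
    stop("'map' must be a retinotopic_map", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(map$visual_angle,
                     file.path(dir, paste0(name, "_angle.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(map$amplitude,
                     file.path(dir, paste0(name, "_amplitude.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(axis = map$axis, pixel_size_mm = map$pixel_size_mm,
                        angle_conversion_factor = map$angle_conversion_factor),
                   file.path(dir, paste0(name, "_meta.yaml")))
  if (png) {
    grDevices::png(file.path(dir, paste0(name, ".png")),
                   width = 600, height = 600)
    on.exit(grDevices::dev.off())
    plot(map)
  }
  invisible(dir)
}

#' Read a retinotopic map written by [write_retinotopic_map()]
#'
#' @param dir directory holding the file set.
#' @param name basename used at write time.
#' @return a `retinotopic_map`.
#' @export
read_retinotopic_map <- function(dir, name = "map") {
  ang <- file.path(dir, paste0(name, "_angle.csv"))
  amp <- file.path(dir, paste0(name, "_amplitude.csv"))
  side <- file.path(dir, paste0(name, "_meta.yaml"))
  for (f in c(ang, amp, side))
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
  meta <- yaml::read_yaml(side)
  structure(list(
    visual_angle = unname(as.matrix(utils::read.csv(ang, header = FALSE))),
    amplitude = unname(as.matrix(utils::read.csv(amp, header = FALSE))),
    axis = meta$axis,
    pixel_size_mm = meta$pixel_size_mm,
    angle_conversion_factor = meta$angle_conversion_factor
  ), class = "retinotopic_map")
}
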