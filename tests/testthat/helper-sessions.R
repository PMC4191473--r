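# Shared fixtures: compact synthetic sessions and maps built in code.

# Small imaging session: 32 x 32 pixels, 3 stimulus cycles at 40 frames per
# cycle. pixel_size_mm = 0.015 gives an angle range of about +/- 8 degrees
# over the default disk ROI at 44.8 deg/mm.
small_session <- function(tilt_deg = 30, mag = 44.8, axis = "elevation",
                          delay = 40, noise_sd = 0, drift = 0, bias = 0,
                          seed = 1L, pixel_size_mm = 0.015) {
  gt <- imaging_ground_truth(tilt_deg = tilt_deg,
                             magnification_deg_per_mm = mag,
                             delay_phase_deg = delay,
                             noise_sd = noise_sd, drift_amplitude = drift,
                             bias_amplitude = bias, seed = seed)
  simulate_imaging_session(gt, nrow = 32, ncol = 32, n_frames = 120,
                           frame_rate_hz = 5, stim_freq_hz = 0.125,
                           direction_axis = axis,
                           pixel_size_mm = pixel_size_mm)
}

small_roi <- function(radius = 12) disk_mask(32, 32, radius)

# Planar retinotopic map built directly (no generator): visual angle is a
# plane with the given gradient (deg/pixel) rotated by theta from the
# row-gradient orientation; amplitude constant.
planar_map <- function(nrow = 32, ncol = 32, grad_deg_per_px = 0.4,
                       theta_deg = 0, axis = "elevation",
                       pixel_size_mm = 0.01, noise_sd = 0, seed = 1L) {
  r0 <- (nrow + 1) / 2; c0 <- (ncol + 1) / 2
  th <- theta_deg * pi / 180
  rr <- matrix(seq_len(nrow), nrow, ncol) - r0
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE) - c0
  v <- grad_deg_per_px * (cos(th) * rr - sin(th) * cc)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + matrix(rnorm(nrow * ncol, sd = noise_sd), nrow, ncol)
  }
  structure(list(visual_angle = v,
                 amplitude = matrix(1, nrow, ncol),
                 axis = axis, pixel_size_mm = pixel_size_mm,
                 angle_conversion_factor = 7.2),
            class = "retinotopic_map")
}

# Brute-force phase-scatter oracle: explicit double loop, no ranking
# shortcuts beyond sorting by amplitude with row-major ties.
scatter_oracle <- function(map, roi, radius = 2.9, max_pixels = 20000) {
  v <- map$visual_angle
  r <- floor(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  nr <- nrow(v); nc <- ncol(v)
  cand <- which(roi, arr.ind = TRUE)
  keep <- cand[, 1] > r & cand[, 1] <= nr - r &
    cand[, 2] > r & cand[, 2] <= nc - r
  cand <- cand[keep, , drop = FALSE]
  amp <- map$amplitude[cand]
  rowmajor <- (cand[, 1] - 1) * nc + cand[, 2]
  cand <- cand[order(-amp, rowmajor), , drop = FALSE]
  cand <- cand[seq_len(min(max_pixels, nrow(cand))), , drop = FALSE]
  devs <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- 0
    for (k in seq_len(nrow(offs)))
      s <- s + v[cand[i, 1] + offs$dr[k], cand[i, 2] + offs$dc[k]]
    devs[i] <- v[cand[i, 1], cand[i, 2]] - s / nrow(offs)
  }
  list(scatter_sd = sd(devs), n_pixels_used = nrow(cand))
}
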