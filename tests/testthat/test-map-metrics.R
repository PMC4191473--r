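# Map metrics: tilt of the zero-phase line, phase scatter, magnification.

test_that("tilt is 0 for a gradient along the reference-perpendicular and 90 when rotated", {
  roi <- disk_mask(32, 32, 12)
  # elevation, gradient purely along rows -> zero line parallel to columns
  m0 <- planar_map(theta_deg = 0, axis = "elevation")
  expect_equal(compute_map_tilt(m0, roi), 0, tolerance = 0.5)
  # gradient along columns -> zero line perpendicular to the reference
  m90 <- planar_map(theta_deg = 90, axis = "elevation")
  expect_equal(compute_map_tilt(m90, roi), 90, tolerance = 0.5)
})

test_that("closed-loop tilt recovery within 1 degree, both axes", {
  roi <- small_roi()
  for (axis in c("elevation", "azimuth"))
    for (th in c(10, 25.7, 44.4)) {
      ses <- small_session(tilt_deg = th, axis = axis)
      map <- retinotopic_map(ses)
      expect_equal(compute_map_tilt(map, roi), th, tolerance = 1,
                   info = sprintf("%s tilt %g", axis, th))
    }
})

test_that("tilt rotation equivariance within 1 degree", {
  roi <- disk_mask(48, 48, 18)
  base <- compute_map_tilt(planar_map(48, 48, theta_deg = 12), roi)
  for (dth in c(10, 23, 41)) {
    t2 <- compute_map_tilt(planar_map(48, 48, theta_deg = 12 + dth), roi)
    expect_equal(t2 - base, dth, tolerance = 1, info = sprintf("delta %g", dth))
  }
})

test_that("tilt errors without a zero crossing in the ROI", {
  m <- planar_map()
  m$visual_angle <- m$visual_angle + 100
  expect_error(compute_map_tilt(m, disk_mask(32, 32, 12)),
               "zero-phase line absent")
})

test_that("the radius-2.9 neighborhood is the full 5x5 square of 25 pixels", {
  fp <- retmap:::scatter_footprint(2.9)
  expect_equal(nrow(fp), 25)
  expect_setequal(unique(fp$dr), -2:2)
  expect_setequal(unique(fp$dc), -2:2)
  # contrast: radius 2 keeps only the diamond-plus-axes set
  expect_equal(nrow(retmap:::scatter_footprint(2)), 13)
})

test_that("scatter is zero on an exactly planar map", {
  m <- planar_map(grad_deg_per_px = 0.37, theta_deg = 28)
  sc <- compute_phase_scatter(m, disk_mask(32, 32, 12))
  expect_lt(sc$scatter_sd, 1e-10)
})

test_that("scatter equals the brute-force oracle and grows with noise", {
  roi <- disk_mask(64, 64, 26)
  prev <- -Inf
  for (sigma in c(0.1, 0.2, 0.4)) {
    m <- planar_map(64, 64, grad_deg_per_px = 0.3, theta_deg = 15,
                    noise_sd = sigma, seed = 21)
    m$amplitude <- matrix(runif(64 * 64), 64, 64)  # exercise the ranking
    got <- compute_phase_scatter(m, roi)
    want <- scatter_oracle(m, roi)
    expect_equal(got$scatter_sd, want$scatter_sd, tolerance = 1e-12)
    expect_identical(got$n_pixels_used, want$n_pixels_used)
    expect_gt(got$scatter_sd, prev)
    prev <- got$scatter_sd
  }
})

test_that("scatter respects the max_pixels cap and is shift invariant", {
  m <- planar_map(64, 64, noise_sd = 0.2, seed = 3)
  roi <- disk_mask(64, 64, 26)
  capped <- compute_phase_scatter(m, roi, max_pixels = 100)
  expect_identical(capped$n_pixels_used, 100L)
  oracle <- scatter_oracle(m, roi, max_pixels = 100)
  expect_equal(capped$scatter_sd, oracle$scatter_sd, tolerance = 1e-12)
  shifted <- m
  shifted$visual_angle <- m$visual_angle + 42
  expect_equal(compute_phase_scatter(shifted, roi)$scatter_sd,
               compute_phase_scatter(m, roi)$scatter_sd, tolerance = 1e-9)
})

test_that("scatter errors when no center has a complete footprint", {
  m <- planar_map()
  tiny <- matrix(FALSE, 32, 32)
  tiny[1:2, 1:2] <- TRUE  # hugs the border: footprints exit the map
  expect_error(compute_phase_scatter(m, tiny), "footprint")
})

test_that("magnification equals gradient over pixel size, closed form", {
  for (g in c(0.3, 0.448)) for (p in c(0.01, 0.02)) {
    m <- planar_map(48, 48, grad_deg_per_px = g, theta_deg = 20,
                    pixel_size_mm = p)
    got <- compute_magnification(m, disk_mask(48, 48, 20))
    expect_equal(got, g / p, tolerance = 0.02 * g / p,
                 info = sprintf("g=%g p=%g", g, p))
  }
})

test_that("magnification is invariant to map tilt", {
  roi <- disk_mask(48, 48, 20)
  vals <- sapply(c(0, 15, 40, 70), function(th)
    compute_magnification(planar_map(48, 48, grad_deg_per_px = 0.448,
                                     theta_deg = th), roi))
  expect_lt(max(vals) - min(vals), 0.02 * mean(vals))
})

test_that("magnification errors on flat maps and unattained levels", {
  flat <- planar_map(grad_deg_per_px = 0)
  expect_error(compute_magnification(flat, disk_mask(32, 32, 12)),
               "zero gradient")
  shallow <- planar_map(grad_deg_per_px = 0.05)  # range +/- 0.8 deg in ROI
  expect_error(compute_magnification(shallow, disk_mask(32, 32, 12)),
               "not attained")
})

test_that("map_metrics bundles all three measures with the pixel cap honored", {
  ses <- small_session(tilt_deg = 25.7)
  met <- map_metrics(retinotopic_map(ses), small_roi())
  expect_s3_class(met, "map_metrics")
  expect_equal(met$tilt_deg, 25.7, tolerance = 1)
  expect_equal(met$magnification_deg_per_mm, 44.8,
               tolerance = 0.02 * 44.8)
  expect_lte(met$n_pixels_used, 20000)
  expect_gte(met$scatter_sd, 0)
  expect_true(met$tilt_deg >= 0 && met$tilt_deg <= 90)
  cf <- coef(met)
  expect_named(cf, c("tilt_deg", "scatter_sd", "magnification_deg_per_mm"))
})
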