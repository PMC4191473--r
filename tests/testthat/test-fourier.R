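# Unit tests for the Fourier stage: boxcar high-pass, fundamental-component
# extraction, bias removal, opposite-direction combination.

make_stack <- function(traces) {
  # traces: list of per-pixel time series, laid out on a 1 x length grid
  n <- length(traces[[1]])
  array(do.call(rbind, traces), dim = c(1, length(traces), n))
}

test_that("boxcar high-pass removes constants and slow ramps, keeps the tone", {
  fr <- 5; f <- 0.125; nfr <- 120
  tt <- (0:(nfr - 1)) / fr
  tone <- 3 * cos(2 * pi * f * tt + 0.5)
  st <- make_stack(list(rep(7, nfr), 0.02 * tt, tone))
  hp <- highpass_boxcar(st, fr, f, window_cycles = 2)
  v <- attr(hp, "valid")
  inside <- v[1]:v[2]
  expect_equal(hp[1, 1, inside], rep(0, length(inside)), tolerance = 1e-12)
  # pure sinusoid at the stimulus frequency is untouched in the interior
  expect_equal(hp[1, 3, inside], tone[inside], tolerance = 1e-10)
  # ramp: residual equals the trace minus a direct moving-average oracle
  w <- 2 * fr / f
  oracle <- sapply(inside, function(i)
    0.02 * tt[i] - mean(0.02 * tt[(i - w / 2 + 1):(i + w / 2)]))
  expect_equal(hp[1, 2, inside], oracle, tolerance = 1e-12)
  # interior ramp residual is the constant half-sample offset of the even
  # centered window, slope / (2 * frame rate) -- tiny relative to the ramp
  expect_lt(max(abs(hp[1, 2, inside])), 0.02 / (2 * fr) + 1e-12)
})

test_that("boxcar window longer than the stack is rejected", {
  st <- array(rnorm(4 * 30), dim = c(2, 2, 30))
  expect_error(highpass_boxcar(st, 5, 0.125, window_cycles = 2), "longer")
})

test_that("extract_fundamental recovers a single tone exactly", {
  fr <- 5; f <- 0.125; nfr <- 120
  tt <- (0:(nfr - 1)) / fr
  st <- make_stack(list(3 * cos(2 * pi * f * tt + 0.5), rep(0, nfr)))
  cm <- extract_fundamental(st, f, fr)
  expect_equal(cm$amplitude[1, 1], 3, tolerance = 1e-12)
  expect_equal(cm$phase_deg[1, 1], 0.5 * 180 / pi, tolerance = 1e-10)
  # zero trace: amplitude 0, phase 0 by convention
  expect_equal(cm$amplitude[1, 2], 0)
  expect_equal(cm$phase_deg[1, 2], 0)
  # amplitude = sqrt(cos^2 + sin^2) pixel-wise
  expect_equal(cm$amplitude, sqrt(cm$cos^2 + cm$sin^2))
})

test_that("extract_fundamental matches the full-spectrum transform oracle", {
  set.seed(11)
  fr <- 5; f <- 0.125; nfr <- 120
  st <- array(rnorm(6 * nfr), dim = c(2, 3, nfr))
  cm <- extract_fundamental(st, f, fr)
  k <- f * nfr / fr  # bin index
  for (r in 1:2) for (c in 1:3) {
    X <- fft(st[r, c, ])
    bin <- X[k + 1] * 2 / nfr
    expect_equal(cm$cos[r, c], Re(bin), tolerance = 1e-10)
    expect_equal(cm$sin[r, c], Im(bin), tolerance = 1e-10)
  }
})

test_that("off-bin stimulus frequencies are rejected", {
  st <- array(rnorm(120), dim = c(1, 1, 120))
  expect_error(extract_fundamental(st, 0.13, 5), "whole number")
})

test_that("remove_bias cancels a constant offset vector exactly", {
  ses <- small_session()
  hp <- highpass_boxcar(ses$stack_fwd, 5, 0.125)
  cm <- extract_fundamental(hp, 0.125, 5)
  biased <- cm
  biased$cos <- cm$cos + 0.7
  biased$sin <- cm$sin - 0.3
  ref <- !disk_mask(32, 32, 14)   # annulus outside the signal region
  out <- remove_bias(biased, ref)
  expect_equal(out$cos, cm$cos, tolerance = 1e-12)
  expect_equal(out$sin, cm$sin, tolerance = 1e-12)
  # reference region mean vector is (0, 0) afterwards
  expect_equal(mean(out$cos[ref]), 0, tolerance = 1e-12)
  expect_equal(mean(out$sin[ref]), 0, tolerance = 1e-12)
  expect_error(remove_bias(cm, matrix(FALSE, 32, 32)), "empty")
})

test_that("estimated bias is within 3 standard errors under noise", {
  ses <- small_session(noise_sd = 0.2, bias = 0.15, seed = 9)
  hp <- highpass_boxcar(ses$stack_fwd, 5, 0.125)
  cm <- extract_fundamental(hp, 0.125, 5)
  ref <- !disk_mask(32, 32, 14)
  out <- remove_bias(cm, ref)
  true_bias <- c(0.15 * cos(ses$ground_truth$bias_phase_deg * pi / 180),
                 0.15 * sin(ses$ground_truth$bias_phase_deg * pi / 180))
  # per-component SE of the reference mean: sqrt(2 sigma^2 / (n_frames m))
  se <- sqrt(2 * 0.2^2 / (40 * sum(ref)))
  err <- sqrt(sum((out$bias_estimate - true_bias)^2))
  expect_lt(err, 3 * sqrt(2) * se)
})

test_that("combine_opposite cancels the delay algebraically", {
  # fwd = d + p, rev = d - p at a single pixel, for several d and p
  base <- extract_fundamental(make_stack(list(rep(0, 120))), 0.125, 5)
  for (d in c(0, 30, 160)) for (p in c(-40, 10, 85)) {
    fwd <- base; rev <- base
    fwd$phase_deg[] <- d + p; fwd$amplitude[] <- 10; fwd$direction <- "fwd"
    rev$phase_deg[] <- d - p; rev$amplitude[] <- 6;  rev$direction <- "rev"
    ab <- combine_opposite(fwd, rev)
    expect_equal(ab$visual_angle[1, 1], p / 7.2, tolerance = 1e-12,
                 info = sprintf("d=%g p=%g", d, p))
    expect_equal(ab$amplitude[1, 1], 8)
  }
})

test_that("combine_opposite validates axis and shape", {
  s1 <- small_session()
  hp <- function(st) highpass_boxcar(st, 5, 0.125)
  f1 <- extract_fundamental(hp(s1$stack_fwd), 0.125, 5, direction = "fwd",
                            axis = "elevation")
  r1 <- extract_fundamental(hp(s1$stack_rev), 0.125, 5, direction = "rev",
                            axis = "azimuth")
  expect_error(combine_opposite(f1, r1), "different axes")
  r2 <- r1; r2$axis <- "elevation"
  r2$phase_deg <- r2$phase_deg[1:16, 1:16]
  expect_error(combine_opposite(f1, r2), "shape")
})

test_that("noiseless pipeline recovers the generator's angle field exactly", {
  for (axis in c("elevation", "azimuth")) {
    ses <- small_session(tilt_deg = 25.7, axis = axis)
    map <- retinotopic_map(ses)
    roi <- disk_mask(32, 32, 12)
    truth <- session_true_angle(ses)
    expect_lt(max(abs((map$visual_angle - truth)[roi])), 1e-9)
  }
})
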