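# VEP and ERG feature extraction.

test_that("average_epochs is the pointwise trial mean", {
  t0 <- seq(0, 0.3, by = 0.001)
  tmpl <- sin(2 * pi * 10 * t0)
  es <- structure(list(time = t0,
                       trials = rbind(tmpl, tmpl, -tmpl),
                       condition = c("a", "a", "b")),
                  class = "epoch_set")
  expect_equal(average_epochs(es, "a"), tmpl, ignore_attr = TRUE)
  # t and -t average to zero
  es2 <- structure(list(time = t0, trials = rbind(tmpl, -tmpl),
                        condition = c("a", "a")), class = "epoch_set")
  expect_equal(average_epochs(es2, "a"), rep(0, length(t0)),
               ignore_attr = TRUE)
  expect_error(average_epochs(es, "zz"), "no trials")
  # noisy epochs: equals an explicit-loop mean oracle exactly
  es3 <- simulate_vep_epochs(c(x = 50), n_trials = 7, noise_sd = 5, seed = 2)
  oracle <- rep(0, length(es3$time))
  for (i in 1:7) oracle <- oracle + es3$trials[i, ]
  expect_equal(average_epochs(es3, "x"), oracle / 7, ignore_attr = TRUE)
})

test_that("vep_amplitude is max minus min over the window", {
  t0 <- seq(0, 0.3, by = 0.001)
  tr <- rep(0, length(t0)); tr[50] <- -60; tr[100] <- 40
  expect_equal(vep_amplitude(tr, t0), 100)
  expect_equal(vep_amplitude(rep(3, 10)), 0)
  expect_error(vep_amplitude(tr, t0, window = c(0.9, 1)), "no samples")
  # invariant to adding a constant
  expect_equal(vep_amplitude(tr + 17, t0), vep_amplitude(tr, t0))
})

test_that("noiseless epochs recover the true amplitude exactly", {
  es <- simulate_vep_epochs(c(c100 = 100, blank = 0), n_trials = 100)
  expect_equal(vep_amplitude(average_epochs(es, "c100"), es$time), 100,
               tolerance = 1e-12)
  expect_lt(vep_amplitude(average_epochs(es, "blank"), es$time), 1e-12)
})

test_that("noisy amplitude recovery stays within the noise envelope", {
  # peak-to-trough of a noisy average overestimates by the extreme-value
  # statistics of the residual noise; the error is bounded by the envelope
  # 2 * (sd/sqrt(n)) * sqrt(2 log n_samples) and is positively biased
  es <- simulate_vep_epochs(c(c100 = 100), n_trials = 100, noise_sd = 20,
                            seed = 4)
  amp <- vep_amplitude(average_epochs(es, "c100"), es$time)
  envelope <- 2 * (20 / sqrt(100)) * sqrt(2 * log(length(es$time)))
  expect_lt(abs(amp - 100), envelope)
  expect_gt(amp, 100)  # systematic positive bias
  # blank condition sits at the noise floor, well below the signal
  es0 <- simulate_vep_epochs(c(blank = 0), n_trials = 100, noise_sd = 20,
                             seed = 4)
  expect_lt(vep_amplitude(average_epochs(es0, "blank"), es0$time), envelope)
})

test_that("amplitude bias shrinks as trials grow", {
  errs <- sapply(c(10, 100, 1000), function(n) {
    es <- simulate_vep_epochs(c(x = 100), n_trials = n, noise_sd = 20,
                              seed = 8)
    abs(vep_amplitude(average_epochs(es, "x"), es$time) - 100)
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 1)
})

test_that("cbi and normalization behave as ratios", {
  expect_equal(compute_cbi(150, 100), 1.5)
  expect_equal(compute_cbi(100, 100), 1)
  expect_equal(round(compute_cbi(197.2, 127.8), 2), 1.54)
  expect_error(compute_cbi(100, 0), "positive")
  expect_equal(normalize_response_curve(c(a = 10, b = 5, c = 2)),
               c(a = 1, b = 0.5, c = 0.2))
  expect_equal(unname(normalize_response_curve(c(a = 4, b = 4, c = 4))),
               rep(1, 3))
  expect_error(normalize_response_curve(c(a = 0, b = 1)), "positive")
})

test_that("a saturating contrast series normalizes to its 100% value", {
  contrasts <- c(100, 75, 50, 25, 10, 5)
  resp <- 120 * contrasts / (contrasts + 20)  # saturating response function
  names(resp) <- paste0("c", contrasts)
  es <- simulate_vep_epochs(resp, n_trials = 20)
  fe <- vep_features(es, reference = "c100")
  expect_equal(unname(fe$normalized_curve),
               unname(resp / resp[["c100"]]), tolerance = 1e-10)
  expect_equal(fe$normalized_curve[["c100"]], 1)
})

test_that("scaling a trace scales amplitudes but not ratios or curves", {
  es <- simulate_vep_epochs(c(a = 80, b = 40), n_trials = 10, noise_sd = 5,
                            seed = 6)
  amp1 <- vep_amplitude(average_epochs(es, "a"), es$time)
  es2 <- es; es2$trials <- es$trials * 3
  amp2 <- vep_amplitude(average_epochs(es2, "a"), es2$time)
  expect_equal(amp2, 3 * amp1, tolerance = 1e-12)
  f1 <- vep_features(es); f2 <- vep_features(es2)
  expect_equal(f2$normalized_curve, f1$normalized_curve, tolerance = 1e-12)
})

test_that("ERG scorer closes the loop on generated a/b amplitudes", {
  for (ab in list(c(216, 454), c(117, 249))) {
    erg <- simulate_erg_trace(ab[1], ab[2])
    f <- erg_wave_amplitudes(erg$trace, erg$time)
    expect_equal(f$a_amplitude, ab[1], tolerance = 1e-6)
    expect_equal(f$b_amplitude, ab[2], tolerance = 1e-6)
    expect_equal(f$ab_ratio, ab[1] / ab[2], tolerance = 1e-6)
    expect_lt(f$a_latency_s, f$b_latency_s)
  }
  expect_equal(round(216 / 454, 2), 0.48)
  expect_equal(round(117 / 249, 2), 0.47)
})

test_that("degenerate ERG inputs follow the documented contract", {
  # no a-wave
  erg <- simulate_erg_trace(0, 100)
  f <- erg_wave_amplitudes(erg$trace, erg$time)
  expect_equal(f$a_amplitude, 0)
  # flat trace: zero amplitudes, NA ratio with a warning
  flat <- simulate_erg_trace(0, 0)
  expect_warning(f0 <- erg_wave_amplitudes(flat$trace, flat$time),
                 "ratio undefined")
  expect_equal(f0$a_amplitude, 0)
  expect_equal(f0$b_amplitude, 0)
  expect_true(is.na(f0$ab_ratio))
  # infeasible request under the trough-to-peak convention
  expect_error(simulate_erg_trace(100, 50), "cannot be smaller")
  expect_error(simulate_erg_trace(100, 200, a_latency_s = 0.08,
                                  b_latency_s = 0.02), "precede")
})

test_that("b-wave convention switch measures from the baseline", {
  erg <- simulate_erg_trace(216, 454)
  f <- erg_wave_amplitudes(erg$trace, erg$time,
                           b_convention = "baseline_to_peak")
  # baseline-to-peak = trough-to-peak minus the a depth (up to baseline tail)
  expect_equal(f$b_amplitude, 454 - 216, tolerance = 1)
})
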