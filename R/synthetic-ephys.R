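# Synthetic VEP epoch sets and ERG traces with known amplitudes.
# Waveform templates are biphasic difference-of-Gaussians shapes: only the
# peak/trough geometry matters to the downstream scorers.

#' Simulate a visually evoked potential epoch set
#'
#' Generates trial epochs whose averaged trace has a known peak-to-trough
#' amplitude per condition. The template is a negative-then-positive
#' difference of Gaussians normalized to unit peak-to-trough, so the true
#' amplitude of condition `k` is exactly `amplitudes[k]` in the noiseless
#' average.
#'
#' @param amplitudes named numeric vector: true peak-to-trough amplitude per
#'   condition (response units, >= 0); names are the condition labels.
#' @param n_trials trials per condition (>= 1).
#' @param noise_sd SD of i.i.d. Gaussian noise added per sample and trial.
#' @param fs_hz sampling rate.
#' @param epoch_s epoch duration, seconds from stimulus reversal at t = 0.
#' @param trough_s,peak_s latencies of the negative and positive template
#'   lobes; the trough must precede the peak and both must lie in the epoch.
#' @param trough_width_s,peak_width_s Gaussian SDs of the two lobes.
#' @param seed RNG seed.
#' @return an object of class `epoch_set`: list with `time` (s), `trials`
#'   (matrix trials x samples) and `condition` (label per trial).
#' @examples
#' es <- simulate_vep_epochs(c(c100 = 100, c50 = 60), n_trials = 10,
#'                           noise_sd = 0)
#' max(average_epochs(es, "c100")) - min(average_epochs(es, "c100"))
#' @export
simulate_vep_epochs <- function(amplitudes,
                                n_trials = 100,
                                noise_sd = 0,
                                fs_hz = 1000,
                                epoch_s = 0.3,
                                trough_s = 0.08,
                                peak_s = 0.16,
                                trough_width_s = 0.015,
                                peak_width_s = 0.03,
                                seed = 1L) {
  if (is.null(names(amplitudes)) || any(!nzchar(names(amplitudes))))
    stop("'amplitudes' must be a named vector of condition amplitudes",
         call. = FALSE)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  if (trough_s >= peak_s)
    stop("template trough must precede the peak", call. = FALSE)
  time <- seq(0, epoch_s, by = 1 / fs_hz)
  tmpl <- -exp(-(time - trough_s)^2 / (2 * trough_width_s^2)) +
    exp(-(time - peak_s)^2 / (2 * peak_width_s^2))
  tmpl <- tmpl / (max(tmpl) - min(tmpl))  # unit peak-to-trough

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  conds <- rep(names(amplitudes), each = n_trials)
  trials <- matrix(rep(rep(amplitudes, each = n_trials), length(time)),
                   nrow = length(conds)) * rep(tmpl, each = length(conds))
  if (noise_sd > 0)
    trials <- trials + matrix(stats::rnorm(length(trials), sd = noise_sd),
                              nrow = nrow(trials))
  structure(list(time = time, trials = trials, condition = conds),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d trials x %d samples (%g s at %g Hz)\n",
              nrow(x$trials), length(x$time), max(x$time) - min(x$time),
              1 / mean(diff(x$time))))
  tb <- table(x$condition)
  cat("  conditions:", paste(sprintf("%s (%d)", names(tb), tb),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Simulate an averaged electroretinogram trace
#'
#' Builds a flash-averaged scotopic ERG: from a flat pre-flash baseline the
#' trace descends to an a-wave trough of depth `a_amp` below baseline, then
#' rises to a b-wave peak `b_amp` above the trough. Component shapes are
#' Gaussians and their weights are calibrated by fixed-point iteration so the
#' realized trough depth and trough-to-peak rise equal the requested
#' amplitudes to machine precision in the noiseless trace.
#'
#' @param a_amp a-wave amplitude: baseline-to-trough depth (response units,
#'   >= 0).
#' @param b_amp b-wave amplitude: trough-to-peak rise (response units, >= 0).
#' @param a_latency_s,b_latency_s post-flash latencies of trough and peak;
#'   the a-wave must precede the b-wave.
#' @param a_width_s,b_width_s Gaussian SDs of the two components.
#' @param fs_hz sampling rate; must be positive.
#' @param pre_s,post_s trace extent before and after the flash (at t = 0).
#' @param n_flashes number of flash responses averaged.
#' @param noise_sd per-flash noise SD (the averaged trace carries
#'   `noise_sd / sqrt(n_flashes)`).
#' @param seed RNG seed.
#' @return list with `time` (s; flash at 0), `trace` (averaged response),
#'   `flash_time` (0) and `n_flashes`; class `erg_trace`.
#' @examples
#' erg <- simulate_erg_trace(a_amp = 216, b_amp = 454)
#' erg_wave_amplitudes(erg$trace, erg$time)
#' @export
simulate_erg_trace <- function(a_amp, b_amp,
                               a_latency_s = 0.020, b_latency_s = 0.080,
                               a_width_s = 0.008, b_width_s = 0.018,
                               fs_hz = 2000, pre_s = 0.1, post_s = 0.3,
                               n_flashes = 6, noise_sd = 0, seed = 1L) {
  if (fs_hz <= 0) stop("'fs_hz' must be positive", call. = FALSE)
  if (a_amp < 0 || b_amp < 0)
    stop("wave amplitudes must be >= 0", call. = FALSE)
  if (a_latency_s >= b_latency_s)
    stop("a-wave latency must precede b-wave latency", call. = FALSE)
  time <- seq(-pre_s, post_s, by = 1 / fs_hz)
  post <- time > 0
  ga <- exp(-(time - a_latency_s)^2 / (2 * a_width_s^2))
  gb <- exp(-(time - b_latency_s)^2 / (2 * b_width_s^2))

  # weights (alpha, beta) such that the post-flash minimum is -a_amp and the
  # post-flash maximum sits b_amp above it. Under the trough-to-peak b-wave
  # convention the trace always returns toward baseline after the trough, so
  # b_amp >= a_amp is required whenever a_amp > 0.
  shape <- function(alpha, beta) -alpha * ga + beta * gb
  if (a_amp > 0 && b_amp < a_amp)
    stop(paste("'b_amp' (trough-to-peak) cannot be smaller than 'a_amp':",
               "the trace returns to baseline after the a-wave trough"),
         call. = FALSE)
  if (a_amp == 0 && b_amp == 0) {
    alpha <- beta <- 0
  } else if (a_amp == 0) {
    # pure b-wave: scale the positive lobe to the requested post-flash range
    g <- gb[post]
    alpha <- 0
    beta <- b_amp / (max(g) - min(g))
  } else if (b_amp == a_amp) {
    # trough only; the return to baseline supplies the full b rise.
    # Depth is taken relative to the realized 50 ms pre-flash baseline,
    # which carries a small tail of the a-wave Gaussian.
    mA <- mean(ga[time < 0 & time >= -0.05])
    alpha <- a_amp / (max(ga[post]) - mA)
    beta <- 0
  } else {
    # general biphasic case: fixed point over the extremum locations;
    # trough depth is measured from the realized 50 ms pre-flash baseline
    # and the b rise trough-to-peak, matching the scorer's definitions
    alpha <- a_amp; beta <- b_amp - a_amp
    ta <- a_latency_s; tb <- b_latency_s
    gA <- function(t) exp(-(t - a_latency_s)^2 / (2 * a_width_s^2))
    gB <- function(t) exp(-(t - b_latency_s)^2 / (2 * b_width_s^2))
    mA <- mean(ga[time < 0 & time >= -0.05])
    mB <- mean(gb[time < 0 & time >= -0.05])
    for (i in 1:50) {
      A <- rbind(c(-(gA(ta) - mA), gB(ta) - mB),
                 c(-(gA(tb) - gA(ta)), gB(tb) - gB(ta)))
      w <- tryCatch(solve(A, c(-a_amp, b_amp)),
                    error = function(e) c(alpha, beta))
      alpha <- w[1]; beta <- w[2]
      tr <- shape(alpha, beta)
      ta_new <- time[post][which.min(tr[post])]
      tb_new <- time[post][which.max(tr[post])]
      if (identical(ta_new, ta) && identical(tb_new, tb)) break
      ta <- ta_new; tb <- tb_new
    }
  }
  clean <- shape(alpha, beta)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  trace <- clean
  if (noise_sd > 0) {
    flashes <- matrix(stats::rnorm(n_flashes * length(time), sd = noise_sd),
                      n_flashes) + rep(clean, each = n_flashes)
    trace <- colMeans(flashes)
  }
  structure(list(time = time, trace = trace, flash_time = 0,
                 n_flashes = n_flashes),
            class = "erg_trace")
}

#' @export
print.erg_trace <- function(x, ...) {
  cat(sprintf("Averaged ERG trace: %d samples, flash at t = %g s (%d flashes)\n",
              length(x$time), x$flash_time, x$n_flashes))
  invisible(x)
}

#' @export
plot.erg_trace <- function(x, ...) {
  graphics::plot(x$time * 1000, x$trace, type = "l",
                 xlab = "time from flash (ms)", ylab = "response", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
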