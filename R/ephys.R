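# Scoring of visually evoked potentials (VEP) and electroretinograms (ERG):
# trial-averaged peak-to-trough amplitudes, contralateral bias index,
# normalized response curves, a-/b-wave amplitudes and their ratio.

#' Average the trials of one condition
#'
#' @param epochs an `epoch_set` (see [simulate_vep_epochs()] or
#'   [read_epoch_set()]).
#' @param condition condition label to select.
#' @return numeric vector: pointwise mean trace across the selected trials.
#' @export
average_epochs <- function(epochs, condition) {
  if (!inherits(epochs, "epoch_set"))
    stop("'epochs' must be an epoch_set", call. = FALSE)
  sel <- epochs$condition == condition
  if (!any(sel))
    stop(sprintf("no trials with condition '%s'", condition), call. = FALSE)
  colMeans(epochs$trials[sel, , drop = FALSE])
}

#' Peak-to-trough amplitude of an averaged trace
#'
#' @param trace numeric vector (averaged response).
#' @param time time base in seconds, same length as `trace`; if `NULL` the
#'   whole trace is used.
#' @param window numeric length-2 analysis interval in seconds (default
#'   0-250 ms post-reversal).
#' @return `max(trace) - min(trace)` over the window.
#' @export
vep_amplitude <- function(trace, time = NULL, window = c(0, 0.25)) {
  if (is.null(time)) {
    seg <- trace
  } else {
    seg <- trace[time >= window[1] & time <= window[2]]
  }
  if (length(seg) == 0) stop("analysis window contains no samples",
                             call. = FALSE)
  max(seg) - min(seg)
}

#' Contralateral bias index
#'
#' Ratio of the contralateral to the ipsilateral response amplitude of one
#' animal; values above 1 indicate the expected contralateral eye dominance.
#'
#' @param amp_contra,amp_ipsi response amplitudes (same units).
#' @return `amp_contra / amp_ipsi`.
#' @export
compute_cbi <- function(amp_contra, amp_ipsi) {
  if (!is.finite(amp_ipsi) || amp_ipsi <= 0)
    stop("ipsilateral amplitude must be positive", call. = FALSE)
  amp_contra / amp_ipsi
}

#' Normalize a response curve to a reference condition
#'
#' Divides each condition's amplitude by the reference condition's amplitude
#' (e.g. the lowest spatial frequency, or 100% contrast), so the reference
#' maps to 1.
#'
#' @param amplitudes named numeric vector of per-condition amplitudes.
#' @param reference name of the reference condition (default: first element).
#' @return named numeric vector of normalized amplitudes.
#' @export
normalize_response_curve <- function(amplitudes, reference = names(amplitudes)[1]) {
  if (is.null(names(amplitudes)))
    stop("'amplitudes' must be named by condition", call. = FALSE)
  if (!reference %in% names(amplitudes))
    stop(sprintf("reference condition '%s' not found", reference),
         call. = FALSE)
  ref <- amplitudes[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference amplitude must be positive", call. = FALSE)
  amplitudes / ref
}

#' VEP features of an epoch set
#'
#' Computes the trial-averaged peak-to-trough amplitude of every condition,
#' the amplitude of the blank (equal-luminance gray) condition as the noise
#' floor, and the response curve normalized to a reference condition.
#'
#' @param epochs an `epoch_set` of VEP trials.
#' @param window analysis window in seconds (see [vep_amplitude()]).
#' @param reference condition to normalize to; default the first condition.
#' @param blank optional label of the blank condition supplying the noise
#'   floor; excluded from the normalized curve.
#' @return object of class `vep_features`: `amplitude` (named vector),
#'   `normalized_curve`, `noise_floor` (or `NA`).
#' @export
vep_features <- function(epochs, window = c(0, 0.25), reference = NULL,
                         blank = NULL) {
  conds <- unique(epochs$condition)
  amps <- vapply(conds, function(cn)
    vep_amplitude(average_epochs(epochs, cn), epochs$time, window),
    numeric(1))
  names(amps) <- conds
  noise <- NA_real_
  curve_amps <- amps
  if (!is.null(blank) && blank %in% conds) {
    noise <- amps[[blank]]
    curve_amps <- amps[setdiff(names(amps), blank)]
  }
  if (is.null(reference)) reference <- names(curve_amps)[1]
  structure(list(
    amplitude = amps,
    normalized_curve = normalize_response_curve(curve_amps, reference),
    noise_floor = noise,
    reference = reference,
    window = window
  ), class = "vep_features")
}

#' @export
print.vep_features <- function(x, ...) {
  cat("VEP features (peak-to-trough amplitudes)\n")
  for (cn in names(x$amplitude))
    cat(sprintf("  %-12s %8.2f%s\n", cn, x$amplitude[[cn]],
                if (cn %in% names(x$normalized_curve))
                  sprintf("  (normalized %.3f)", x$normalized_curve[[cn]])
                else ""))
  if (is.finite(x$noise_floor))
    cat(sprintf("  noise floor (blank): %.2f\n", x$noise_floor))
  invisible(x)
}

#' ERG a- and b-wave amplitudes
#'
#' Scores an averaged flash response: the a-wave amplitude is the drop from
#' the pre-flash baseline to the trace minimum in the a-window, and the
#' b-wave amplitude is, under the default trough-to-peak convention, the rise
#' from that trough to the trace maximum in the b-window
#' (`"baseline_to_peak"` measures it from the baseline instead). The baseline
#' is the mean over `baseline_s` seconds immediately preceding the flash.
#' Degenerate inputs (flat trace, no negative deflection) report zero
#' amplitudes, and the a/b ratio is `NA` with a warning when the b-wave
#' amplitude is zero.
#'
#' @param trace averaged ERG trace.
#' @param time time base in seconds.
#' @param flash_time flash onset within `time` (default 0).
#' @param a_window,b_window post-flash search intervals (seconds after the
#'   flash) for the a-wave trough and b-wave peak; the b-window maximum must
#'   not precede the a-window minimum.
#' @param baseline_s length of the pre-flash baseline segment.
#' @param b_convention `"trough_to_peak"` (default) or `"baseline_to_peak"`.
#' @return object of class `erg_features`: `a_amplitude`, `b_amplitude`,
#'   `ab_ratio`, `a_latency_s`, `b_latency_s` (relative to the flash).
#' @export
erg_wave_amplitudes <- function(trace, time, flash_time = 0,
                                a_window = c(0.005, 0.045),
                                b_window = c(0.030, 0.150),
                                baseline_s = 0.05,
                                b_convention = c("trough_to_peak",
                                                 "baseline_to_peak")) {
  b_convention <- match.arg(b_convention)
  if (length(trace) != length(time))
    stop("'trace' and 'time' must have the same length", call. = FALSE)
  if (a_window[1] < 0 || b_window[1] < 0)
    stop("search windows must start after the flash", call. = FALSE)
  base_sel <- time < flash_time & time >= flash_time - baseline_s
  if (!any(base_sel))
    stop("no pre-flash baseline segment available", call. = FALSE)
  baseline <- mean(trace[base_sel])
  ta <- time - flash_time
  a_sel <- which(ta >= a_window[1] & ta <= a_window[2])
  b_sel <- which(ta >= b_window[1] & ta <= b_window[2])
  if (length(a_sel) == 0 || length(b_sel) == 0)
    stop("search window contains no samples", call. = FALSE)
  ia <- a_sel[which.min(trace[a_sel])]
  ib <- b_sel[which.max(trace[b_sel])]
  if (time[ib] < time[ia])
    stop("ordering violation: b-window maximum precedes the a-window minimum",
         call. = FALSE)
  a_amp <- max(0, baseline - trace[ia])
  b_amp <- if (b_convention == "trough_to_peak")
    max(0, trace[ib] - trace[ia]) else max(0, trace[ib] - baseline)
  ratio <- if (b_amp > 0) a_amp / b_amp else {
    warning("b-wave amplitude is zero; a/b ratio undefined (NA)")
    NA_real_
  }
  structure(list(
    a_amplitude = a_amp,
    b_amplitude = b_amp,
    ab_ratio = ratio,
    a_latency_s = ta[ia],
    b_latency_s = ta[ib],
    baseline = baseline,
    b_convention = b_convention
  ), class = "erg_features")
}

#' @export
print.erg_features <- function(x, ...) {
  cat(sprintf(paste0(
    "ERG features (%s b-wave convention)\n",
    "  a-wave: %8.2f  at %5.1f ms\n",
    "  b-wave: %8.2f  at %5.1f ms\n",
    "  a/b ratio: %s\n"),
    gsub("_", "-", x$b_convention), x$a_amplitude, x$a_latency_s * 1000,
    x$b_amplitude, x$b_latency_s * 1000,
    if (is.na(x$ab_ratio)) "NA" else sprintf("%.2f", x$ab_ratio)))
  invisible(x)
}
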