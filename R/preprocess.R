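#' Savitzky-Golay smoothing of a trace
#'
#' Least-squares local-polynomial smoothing.  The window is specified in
#' milliseconds and converted to an odd number of samples; traces that are
#' themselves polynomials of degree at most `polyorder` pass through
#' unchanged (including at the edges, which are handled by polynomial fits
#' on truncated windows).
#'
#' @param trace Numeric vector.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param window_ms Smoothing window, ms (default 2.05 ms, i.e. 41 samples
#'   at 20 kHz).
#' @param polyorder Polynomial order (default 3).
#' @return Smoothed numeric vector, same length.
#' @export
savgol_filter_trace <- function(trace, sampling_rate_hz,
                                window_ms = 2.05, polyorder = 3) {
  w <- round(window_ms * sampling_rate_hz / 1000)
  if (w %% 2 == 0) w <- w + 1
  if (w < polyorder + 2) {
    stop("filter window must cover at least `polyorder` + 2 samples",
         call. = FALSE)
  }
  if (length(trace) < w) {
    stop("trace shorter than the filter window", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(trace, p = polyorder, n = w))
}

#' Detect action-potential contamination in a sweep
#'
#' A sweep is flagged when any sample reaches the absolute voltage threshold
#' or the slope reaches the dV/dt threshold (both inclusive, `>=`).  Flagged
#' sweeps are excluded from cycle averaging downstream.
#'
#' @param sweep A [voltage_sweep()].
#' @param v_threshold_mv Absolute voltage threshold, mV (default -20;
#'   uEPSPs recorded near -65 mV stay far below this).
#' @param dvdt_threshold_mv_per_ms Slope threshold, mV/ms (default 80; the
#'   fastest regenerative uEPSP rises stay below this while the spike
#'   upstroke exceeds it).
#' @return A list with `flagged` (logical) and `indices` (sample indices
#'   that crossed either threshold).
#' @export
detect_action_potentials <- function(sweep, v_threshold_mv = -20,
                                     dvdt_threshold_mv_per_ms = 80) {
  v <- sweep$samples
  dvdt <- c(0, diff(v)) * sweep$sampling_rate_hz / 1000
  hit <- which(v >= v_threshold_mv | dvdt >= dvdt_threshold_mv_per_ms)
  list(flagged = length(hit) > 0, indices = hit)
}

#' Remove uncaging light artifacts from a linescan
#'
#' Blanks the lines within a window around each uncaging pulse and replaces
#' them, on both channels, by linear interpolation across the gap; the
#' artifact mask is updated.  Overlapping blank windows are merged.
#'
#' @param scan A [linescan()].
#' @param pulse_times_ms Pulse onsets, ms; defaults to the scan's own onsets.
#' @param pulse_duration_ms Pulse duration, ms (default 0.5).
#' @param blank_window_ms Extra blanking on each side of a pulse, ms;
#'   defaults to one line period.
#' @return The cleaned [linescan()].
#' @export
remove_uncaging_artifacts <- function(scan,
                                      pulse_times_ms = scan$onset_times_ms,
                                      pulse_duration_ms = 0.5,
                                      blank_window_ms = scan$line_period_ms) {
  if (!length(pulse_times_ms)) return(scan)
  t <- linescan_times(scan)
  dur <- length(scan$green) * scan$line_period_ms
  if (any(pulse_times_ms < 0) || any(pulse_times_ms > dur)) {
    stop("pulse times must lie within the record", call. = FALSE)
  }
  half <- scan$line_period_ms / 2
  mask <- rep(FALSE, length(t))
  for (on in pulse_times_ms) {
    mask <- mask | (t + half > on - blank_window_ms &
                      t - half < on + pulse_duration_ms + blank_window_ms)
  }
  interp_gap <- function(y) {
    if (!any(mask)) return(y)
    good <- which(!mask)
    if (!length(good)) stop("all lines masked", call. = FALSE)
    y[mask] <- stats::approx(good, y[good], xout = which(mask), rule = 2)$y
    y
  }
  scan$green <- interp_gap(scan$green)
  scan$red <- interp_gap(scan$red)
  scan$artifact_mask <- scan$artifact_mask | mask
  scan
}

#' Baseline-subtract and average sweeps across cycles
#'
#' Each sweep is baseline-subtracted using the mean over a pre-stimulus
#' window, sweeps flagged as containing action potentials are excluded, and
#' the remainder are averaged pointwise.  All sweeps must share condition,
#' active-location count and length.
#'
#' @param sweeps List of [voltage_sweep()] objects.
#' @param baseline_window_ms Pre-stimulus baseline window, ms (default 50,
#'   ending at the first onset).
#' @param exclude_aps Exclude action-potential-contaminated sweeps
#'   (default `TRUE`).
#' @param v_threshold_mv,dvdt_threshold_mv_per_ms Passed to
#'   [detect_action_potentials()].
#' @return A baseline-subtracted mean [voltage_sweep()]; its `meta` records
#'   `n_averaged` and `n_excluded`.
#' @export
baseline_and_average <- function(sweeps, baseline_window_ms = 50,
                                 exclude_aps = TRUE,
                                 v_threshold_mv = -20,
                                 dvdt_threshold_mv_per_ms = 80) {
  if (!length(sweeps)) stop("no sweeps supplied", call. = FALSE)
  cond <- unique(vapply(sweeps, `[[`, character(1), "condition"))
  kk <- unique(vapply(sweeps, `[[`, integer(1), "k_active"))
  lens <- unique(vapply(sweeps, function(s) length(s$samples), integer(1)))
  if (length(cond) > 1 || length(kk) > 1 || length(lens) > 1) {
    stop("sweeps must share condition, k and length", call. = FALSE)
  }
  keep <- rep(TRUE, length(sweeps))
  if (exclude_aps) {
    keep <- !vapply(sweeps, function(s) {
      detect_action_potentials(s, v_threshold_mv,
                               dvdt_threshold_mv_per_ms)$flagged
    }, logical(1))
  }
  if (!any(keep)) {
    stop("all sweeps excluded (action potentials); group cannot be analyzed",
         call. = FALSE)
  }
  fs <- sweeps[[1]]$sampling_rate_hz
  onset <- sweeps[[1]]$onset_times_ms[1]
  i1 <- max(1, round((onset - baseline_window_ms) * fs / 1000) + 1)
  i2 <- round(onset * fs / 1000)
  if (i2 < i1) stop("baseline window is empty", call. = FALSE)
  subtracted <- lapply(sweeps[keep], function(s) {
    s$samples - mean(s$samples[i1:i2])
  })
  avg <- Reduce(`+`, subtracted) / length(subtracted)
  out <- sweeps[keep][[1]]
  out$samples <- avg
  out$meta$n_averaged <- sum(keep)
  out$meta$n_excluded <- sum(!keep)
  out$meta$cycle <- NULL
  out
}
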