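#' Extract unitary responses from an averaged asynchronous sweep
#'
#' Slices the mean asynchronous sweep into per-location segments aligned to
#' their uncaging onsets and re-baselines each segment to the few
#' milliseconds immediately preceding its own onset, so that residual decay
#' from the previous event is treated as baseline.
#'
#' @param mean_sweep Baseline-subtracted mean asynchronous [voltage_sweep()]
#'   (see [baseline_and_average()]).
#' @param onset_times_ms Onset times, ms; defaults to the sweep's own onsets.
#' @param n_locations Expected number of onsets; an error is raised when the
#'   supplied onsets do not match (default: the number of onsets present).
#' @param segment_ms Segment duration, ms; defaults to the smallest
#'   inter-onset interval.
#' @param rebaseline_ms Per-segment baseline window, ms (default 5).
#' @return A list of unitary-response objects, each with elements `segment`
#'   (mV, starting at its onset), `location_index`, `sampling_rate_hz` and
#'   `duration_ms`.
#' @export
extract_unitaries <- function(mean_sweep,
                              onset_times_ms = mean_sweep$onset_times_ms,
                              n_locations = length(onset_times_ms),
                              segment_ms = NULL,
                              rebaseline_ms = 5) {
  if (length(onset_times_ms) != n_locations) {
    stop(sprintf("expected %d onsets, got %d", n_locations,
                 length(onset_times_ms)), call. = FALSE)
  }
  fs <- mean_sweep$sampling_rate_hz
  if (is.null(segment_ms)) {
    segment_ms <- min(diff(onset_times_ms)) * (fs / 1000)
    segment_ms <- floor(segment_ms) * 1000 / fs
  }
  seg_n <- floor(segment_ms * fs / 1000)
  base_n <- round(rebaseline_ms * fs / 1000)
  v <- mean_sweep$samples
  lapply(seq_len(n_locations), function(j) {
    i0 <- round(onset_times_ms[j] * fs / 1000)   # sample index of the onset
    if (i0 + seg_n > length(v)) {
      stop(sprintf("onset %d too close to the sweep end (need %d samples)",
                   j, seg_n), call. = FALSE)
    }
    b1 <- max(1, i0 - base_n + 1)
    seg <- v[i0 + seq_len(seg_n)] - mean(v[b1:i0])
    structure(
      list(segment = seg, location_index = j, sampling_rate_hz = fs,
           duration_ms = seg_n * 1000 / fs),
      class = "unitary_response"
    )
  })
}

#' Arithmetic-sum trace for k locations
#'
#' Constructs the expected linear response to near-synchronous uncaging at
#' `k` locations by staggering the first `k` unitary responses by the
#' onset-to-onset spacing and summing them on the common sample grid
#' (fractional delays by linear interpolation, see [shift_trace()]).
#'
#' @param unitaries List from [extract_unitaries()].
#' @param k Number of locations to sum, `1..length(unitaries)`.
#' @param onset_stagger_ms Onset-to-onset stagger, ms (default 0.82).
#' @return Numeric trace, same length as one segment.
#' @export
arithmetic_sum <- function(unitaries, k, onset_stagger_ms = 0.82) {
  if (k < 1 || k > length(unitaries)) {
    stop("`k` out of range", call. = FALSE)
  }
  fs <- unitaries[[1]]$sampling_rate_hz
  out <- unitaries[[1]]$segment
  if (k > 1) {
    for (j in 2:k) {
      out <- out + shift_trace(unitaries[[j]]$segment,
                               (j - 1) * onset_stagger_ms, fs)
    }
  }
  out
}

#' Peak amplitude of a baseline-subtracted trace
#'
#' Maximum of the trace within a search window expressed relative to the
#' trace start (the stimulus onset for measurement traces).
#'
#' @param trace Numeric vector (baseline-subtracted, mV).
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param window_ms Two-element window `c(from, to)` in ms (default
#'   `c(0, 100)`).
#' @return Peak amplitude, mV.
#' @export
measure_peak <- function(trace, sampling_rate_hz, window_ms = c(0, 100)) {
  i1 <- round(window_ms[1] * sampling_rate_hz / 1000) + 1
  i2 <- min(length(trace), round(window_ms[2] * sampling_rate_hz / 1000) + 1)
  if (i2 < i1 || i1 < 1 || i1 > length(trace)) {
    stop("empty or out-of-range search window", call. = FALSE)
  }
  max(trace[i1:i2])
}

#' Time integral of a baseline-subtracted trace
#'
#' Trapezoidal integral over a fixed horizon from the trace start (100 ms by
#' default, matching the somatic-depolarization integral).
#'
#' @param trace Numeric vector (baseline-subtracted, mV).
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param integration_ms Integration horizon, ms (default 100).
#' @return Integral in mV*ms.
#' @export
measure_integral <- function(trace, sampling_rate_hz, integration_ms = 100) {
  n <- round(integration_ms * sampling_rate_hz / 1000) + 1
  if (n > length(trace)) {
    stop("trace does not cover the integration horizon", call. = FALSE)
  }
  h <- 1000 / sampling_rate_hz
  y <- trace[seq_len(n)]
  h * (sum(y) - (y[1] + y[n]) / 2)
}

#' Min-max scaling against a reference series
#'
#' Scales values as `(x - min(ref)) / (max(ref) - min(ref))`.  The reference
#' (the asynchronous separate-response measurements) is mapped onto
#' `[0, 1]`; the target series (near-synchronous measurements scaled with
#' the reference's extrema) may exceed that range.  Scaling is used for
#' display only; the nonlinearity statistic is computed from unscaled
#' measures.
#'
#' @param values Numeric vector to scale.
#' @param reference_values Reference series supplying the extrema
#'   (default: `values` itself).
#' @return Scaled numeric vector.
#' @export
minmax_scale <- function(values, reference_values = values) {
  rng <- range(reference_values)
  if (!(diff(rng) > 0)) {
    stop("reference series is constant; scale is degenerate", call. = FALSE)
  }
  (values - rng[1]) / diff(rng)
}

# assemble the long-format observed/expected series for one dendrite
build_summation_series <- function(dendrite_id, M_amp, A_amp, M_int, A_int) {
  n <- length(M_amp)
  tibble::tibble(
    dendrite_id = dendrite_id,
    k = rep(seq_len(n), 2),
    measure = rep(c("amplitude", "integral"), each = n),
    observed = c(M_amp, M_int),
    expected = c(A_amp, A_int),
    scaled_observed = c(minmax_scale(M_amp, A_amp), minmax_scale(M_int, A_int)),
    scaled_expected = c(minmax_scale(A_amp), minmax_scale(A_int))
  )
}
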