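#' Voltage sweep record
#'
#' A single somatic voltage recording (one stimulation sweep) together with
#' the stimulus timing and bookkeeping metadata.  Samples are absolute
#' membrane potential in mV on a uniform grid.
#'
#' @param samples Numeric vector of membrane potential, mV.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param condition `"asynchronous"` or `"near_synchronous"`.
#' @param onset_times_ms Uncaging pulse onset times within the sweep, ms;
#'   must be strictly increasing and inside the sweep.
#' @param k_active For near-synchronous sweeps, the number of co-active
#'   locations; `NA` for asynchronous sweeps.
#' @param meta Named list of metadata (dendrite id, cycle index, drug
#'   condition label, covariates...).
#'
#' @return An object of class `voltage_sweep`.
#' @export
voltage_sweep <- function(samples, sampling_rate_hz,
                          condition = c("asynchronous", "near_synchronous"),
                          onset_times_ms = numeric(),
                          k_active = NA_integer_,
                          meta = list()) {
  condition <- match.arg(condition)
  if (sampling_rate_hz <= 0) stop("sampling rate must be positive", call. = FALSE)
  dur <- length(samples) / sampling_rate_hz * 1000
  if (length(onset_times_ms)) {
    if (is.unsorted(onset_times_ms, strictly = TRUE)) {
      stop("`onset_times_ms` must be strictly increasing", call. = FALSE)
    }
    if (min(onset_times_ms) < 0 || max(onset_times_ms) >= dur) {
      stop("onset times must lie within the sweep", call. = FALSE)
    }
  }
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate_hz = sampling_rate_hz,
      condition = condition,
      onset_times_ms = as.numeric(onset_times_ms),
      k_active = as.integer(k_active),
      meta = meta
    ),
    class = "voltage_sweep"
  )
}

#' @export
print.voltage_sweep <- function(x, ...) {
  cat(sprintf("<voltage_sweep> %s%s: %d samples @ %g Hz (%.1f ms), %d onsets\n",
              x$condition,
              if (!is.na(x$k_active)) sprintf(" k=%d", x$k_active) else "",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz * 1000,
              length(x$onset_times_ms)))
  invisible(x)
}

#' Two-channel calcium linescan record
#'
#' Fluorescence versus time from a linescan across a dendrite: a
#' calcium-sensitive green channel and a calcium-insensitive red reference
#' channel, plus the uncaging pulse times and a per-line artifact mask.
#'
#' @param green,red Numeric vectors of fluorescence (au), equal length.
#' @param line_period_ms Time per scanned line, ms.
#' @param onset_times_ms Uncaging pulse onsets, ms.
#' @param artifact_mask Logical vector marking lines contaminated by the
#'   uncaging light artifact; defaults to all `FALSE`.
#' @param condition,k_active,meta As in [voltage_sweep()].
#'
#' @return An object of class `linescan`.
#' @export
linescan <- function(green, red, line_period_ms,
                     onset_times_ms = numeric(),
                     artifact_mask = NULL,
                     condition = c("asynchronous", "near_synchronous"),
                     k_active = NA_integer_,
                     meta = list()) {
  condition <- match.arg(condition)
  if (length(green) != length(red)) {
    stop("green and red channels must have equal length", call. = FALSE)
  }
  if (line_period_ms <= 0) stop("`line_period_ms` must be positive", call. = FALSE)
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, length(green))
  if (length(artifact_mask) != length(green)) {
    stop("`artifact_mask` must match the channel length", call. = FALSE)
  }
  structure(
    list(
      green = as.numeric(green),
      red = as.numeric(red),
      line_period_ms = line_period_ms,
      onset_times_ms = as.numeric(onset_times_ms),
      artifact_mask = as.logical(artifact_mask),
      condition = condition,
      k_active = as.integer(k_active),
      meta = meta
    ),
    class = "linescan"
  )
}

#' @export
print.linescan <- function(x, ...) {
  cat(sprintf("<linescan> %s%s: %d lines @ %.2f ms (%.0f ms), %d masked\n",
              x$condition,
              if (!is.na(x$k_active)) sprintf(" k=%d", x$k_active) else "",
              length(x$green), x$line_period_ms,
              length(x$green) * x$line_period_ms, sum(x$artifact_mask)))
  invisible(x)
}

# time axis (ms) of a linescan, line centres
linescan_times <- function(ls) {
  (seq_along(ls$green) - 0.5) * ls$line_period_ms
}
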