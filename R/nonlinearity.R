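#' Percent nonlinearity of dendritic summation
#'
#' The nonlinearity index: the mean, over `i = 2..n`, of the relative
#' deviation of the measured near-synchronous response from its expectation,
#'
#' \deqn{\%NL = \frac{\sum_{i=2}^{n} (M_i/A_i - 1)}{n - 1} \times 100\%}
#'
#' where `M[i]` is the measured response with `i` co-active locations and
#' `A[i]` the corresponding arithmetic-sum (or interpolated) expectation.
#' Positive values indicate supralinear, negative sublinear summation.  The
#' `i = 1` term never contributes.  Terms with a degenerate (near-zero)
#' expectation are excluded and the divisor reduced accordingly; the number
#' of terms used and any excluded indices are attached as attributes
#' `n_used` and `excluded`.
#'
#' @param M Measured responses, `i = 1..n` (`n >= 2`).
#' @param A Expected responses, same length.
#' @param eps Expectations with `|A[i]| <= eps` are excluded (default 1e-9).
#' @return Percent nonlinearity (numeric scalar).
#' @examples
#' percent_nonlinearity(c(1, 3, 6), c(1, 2, 4))  # 50
#' @export
percent_nonlinearity <- function(M, A, eps = 1e-9) {
  n <- length(M)
  if (length(A) != n) stop("`M` and `A` must have equal length", call. = FALSE)
  if (n < 2) stop("need at least two locations", call. = FALSE)
  idx <- 2:n
  ok <- abs(A[idx]) > eps
  if (!any(ok)) {
    stop("all expectation terms are degenerate; statistic undefined",
         call. = FALSE)
  }
  terms <- M[idx][ok] / A[idx][ok] - 1
  out <- sum(terms) / sum(ok) * 100
  attr(out, "n_used") <- sum(ok)
  attr(out, "excluded") <- idx[!ok]
  out
}

#' Delta-F/A quantification of a calcium linescan
#'
#' The change in calcium-sensitive (green) fluorescence from its
#' pre-stimulus baseline, normalized by the calcium-insensitive (red)
#' reference fluorescence: `dF = max over the peak window of
#' (green - baseline)` with the baseline taken as the mean green over the
#' pre-stimulus window, and `A = mean red over the whole record`.  The green
#' channel is Savitzky-Golay smoothed before the peak is taken.  The
#' linescan should be artifact-cleaned first (see
#' [remove_uncaging_artifacts()]).
#'
#' @param scan A [linescan()].
#' @param baseline_window_ms Pre-stimulus baseline window, ms (default 50,
#'   ending at the first onset).
#' @param peak_window_ms Two-element window `c(from, to)`, ms, within which
#'   the peak is searched; default from the first onset to the record end.
#' @param smooth_window_ms Green-channel smoothing window, ms (default 10);
#'   set to 0 to skip smoothing.
#' @param polyorder Smoothing polynomial order (default 3).
#' @return Peak delta-F/A (dimensionless).
#' @export
delta_f_over_a <- function(scan, baseline_window_ms = 50,
                           peak_window_ms = NULL,
                           smooth_window_ms = 10, polyorder = 3) {
  t <- linescan_times(scan)
  a <- mean(scan$red)
  if (!(a > 0)) stop("red-channel denominator is degenerate", call. = FALSE)
  onset <- if (length(scan$onset_times_ms)) scan$onset_times_ms[1] else
    baseline_window_ms
  base_idx <- t >= onset - baseline_window_ms & t < onset
  if (!any(base_idx)) stop("baseline window is empty", call. = FALSE)
  g <- scan$green
  if (smooth_window_ms > 0) {
    fs_lines <- 1000 / scan$line_period_ms
    g <- savgol_filter_trace(g, fs_lines, smooth_window_ms, polyorder)
  }
  if (is.null(peak_window_ms)) peak_window_ms <- c(onset, max(t))
  peak_idx <- t >= peak_window_ms[1] & t <= peak_window_ms[2]
  if (!any(peak_idx)) stop("peak window is empty", call. = FALSE)
  df <- max(g[peak_idx]) - mean(g[base_idx])
  df / a
}

#' Interpolated linear expectation for calcium transients
#'
#' Because the calcium signal does not return to baseline between
#' asynchronous stimuli, an arithmetic sum cannot be constructed for the
#' calcium channel.  The linear expectation is instead interpolated between
#' the transient measured with a single near-synchronously uncaged location
#' and the transient at the end of the asynchronous record, which
#' encompasses all `n` uncaging events:
#' `expected[i] = dfa_1 + (i - 1) / (n - 1) * (dfa_async_n - dfa_1)`.
#'
#' @param dfa_1_sync Peak delta-F/A with one location uncaged
#'   (near-synchronous condition, first sweep).
#' @param dfa_async_n Peak delta-F/A at the end of the asynchronous record
#'   (all `n` locations).
#' @param n Number of locations (>= 2).
#' @return Numeric vector `expected[1..n]`; the endpoints reproduce the two
#'   inputs exactly.
#' @export
interpolate_expected_calcium <- function(dfa_1_sync, dfa_async_n, n) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  dfa_1_sync + (seq_len(n) - 1) / (n - 1) * (dfa_async_n - dfa_1_sync)
}

#' Percent nonlinearity of calcium transients
#'
#' Applies [percent_nonlinearity()] with the interpolated linear expectation
#' in place of the arithmetic sum.  The first term is identically zero since
#' `expected[1]` equals the measured single-location transient.
#'
#' @param dfa Measured peak delta-F/A for `i = 1..n` near-synchronous
#'   locations.
#' @param expected Interpolated expectation from
#'   [interpolate_expected_calcium()].
#' @param eps Degenerate-expectation tolerance.
#' @return Percent nonlinearity.
#' @export
calcium_nonlinearity <- function(dfa, expected, eps = 1e-9) {
  percent_nonlinearity(dfa, expected, eps = eps)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the measurement pipeline.
#'
#' @param filter_window_ms,filter_polyorder Savitzky-Golay parameters for
#'   the voltage measurement traces.
#' @param filter_sweeps Apply the filter to each raw sweep before averaging
#'   (`FALSE` by default: the filter is instead applied identically to the
#'   measured near-synchronous and arithmetic-sum traces, which avoids the
#'   smoothing window straddling adjacent asynchronous events during
#'   unitary extraction).
#' @param v_threshold_mv,dvdt_threshold_mv_per_ms Action-potential exclusion
#'   thresholds.
#' @param baseline_window_ms Pre-stimulus baseline window, ms.
#' @param rebaseline_ms Per-unitary re-baselining window, ms.
#' @param peak_window_ms Peak search window relative to the first onset, ms.
#' @param integration_ms Voltage integration horizon, ms.
#' @param ca_baseline_window_ms,ca_smooth_window_ms Calcium baseline and
#'   smoothing windows, ms.
#' @param eps Degenerate-denominator tolerance for the nonlinearity index.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(filter_window_ms = 2.05,
                            filter_polyorder = 3,
                            filter_sweeps = FALSE,
                            v_threshold_mv = -20,
                            dvdt_threshold_mv_per_ms = 80,
                            baseline_window_ms = 50,
                            rebaseline_ms = 5,
                            peak_window_ms = c(0, 100),
                            integration_ms = 100,
                            ca_baseline_window_ms = 50,
                            ca_smooth_window_ms = 10,
                            eps = 1e-9) {
  cfg <- as.list(environment())
  if (any(c(cfg$filter_window_ms, cfg$baseline_window_ms, cfg$rebaseline_ms,
            cfg$integration_ms) <= 0)) {
    stop("analysis windows must be positive", call. = FALSE)
  }
  structure(cfg, class = "analysis_config")
}

#' Full per-dendrite nonlinearity analysis
#'
#' Runs the complete measurement chain for one dendrite: cycle averaging
#' with action-potential exclusion, unitary extraction from the asynchronous
#' condition, arithmetic-sum construction, identical filtering of observed
#' and expected traces, peak/integral measurement, and the percent
#' nonlinearity for amplitude and integral.  When linescans are supplied,
#' uncaging artifacts are removed, peak delta-F/A is measured per location
#' count, the linear expectation is interpolated, and the calcium
#' nonlinearity is added.
#'
#' @param sweeps List of [voltage_sweep()] objects covering the asynchronous
#'   condition and near-synchronous sweeps for every `k` (repeated cycles
#'   allowed).
#' @param linescans Optional list of [linescan()] objects (matching
#'   conditions), or `NULL` for a voltage-only analysis.
#' @param protocol The [uncaging_protocol()].
#' @param config An [analysis_config()].
#' @param dendrite_id Identifier for the output row; defaults to the id in
#'   the sweep metadata.
#' @return An object of class `dendrite_analysis`: a list with `result`
#'   (one-row tibble with the nonlinearity percentages), `series` (the
#'   long-format observed/expected summation series) and `calcium` (per-k
#'   delta-F/A tibble, or `NULL`).  Use [glance()] / [tidy()] to extract
#'   the tibbles.
#' @export
analyze_dendrite <- function(sweeps, linescans = NULL, protocol,
                             config = analysis_config(),
                             dendrite_id = NULL) {
  n_loc <- protocol$n_locations
  fs <- protocol$sampling_rate_hz
  if (is.null(dendrite_id)) {
    dendrite_id <- sweeps[[1]]$meta$dendrite_id %||% "dendrite"
  }
  conds <- vapply(sweeps, `[[`, character(1), "condition")
  async <- sweeps[conds == "asynchronous"]
  ns <- sweeps[conds == "near_synchronous"]
  if (!length(async)) stop("no asynchronous sweeps supplied", call. = FALSE)
  if (!length(ns)) stop("no near-synchronous sweeps supplied", call. = FALSE)

  if (config$filter_sweeps) {
    filt <- function(s) {
      s$samples <- savgol_filter_trace(s$samples, fs, config$filter_window_ms,
                                       config$filter_polyorder)
      s
    }
    async <- lapply(async, filt)
    ns <- lapply(ns, filt)
  }

  avg <- function(group) {
    baseline_and_average(group, config$baseline_window_ms,
                         v_threshold_mv = config$v_threshold_mv,
                         dvdt_threshold_mv_per_ms =
                           config$dvdt_threshold_mv_per_ms)
  }
  mean_async <- avg(async)
  unitaries <- extract_unitaries(mean_async, n_locations = n_loc,
                                 rebaseline_ms = config$rebaseline_ms)
  seg_n <- length(unitaries[[1]]$segment)

  measure_both <- function(trace) {
    tr <- savgol_filter_trace(trace, fs, config$filter_window_ms,
                              config$filter_polyorder)
    c(peak = measure_peak(tr, fs, config$peak_window_ms),
      integral = measure_integral(tr, fs, config$integration_ms))
  }

  ks <- vapply(ns, `[[`, integer(1), "k_active")
  M_amp <- M_int <- A_amp <- A_int <- numeric(n_loc)
  for (k in seq_len(n_loc)) {
    grp <- ns[ks == k]
    if (!length(grp)) {
      stop(sprintf("dendrite %s: missing near-synchronous sweeps for k = %d",
                   dendrite_id, k), call. = FALSE)
    }
    mean_k <- avg(grp)
    i0 <- round(mean_k$onset_times_ms[1] * fs / 1000)
    if (i0 + seg_n > length(mean_k$samples)) {
      stop("near-synchronous sweep too short for the analysis segment",
           call. = FALSE)
    }
    m <- measure_both(mean_k$samples[i0 + seq_len(seg_n)])
    a <- measure_both(arithmetic_sum(unitaries, k, protocol$onset_stagger_ms))
    M_amp[k] <- m["peak"]; M_int[k] <- m["integral"]
    A_amp[k] <- a["peak"]; A_int[k] <- a["integral"]
  }

  amp_nl <- percent_nonlinearity(M_amp, A_amp, eps = config$eps)
  int_nl <- percent_nonlinearity(M_int, A_int, eps = config$eps)
  series <- build_summation_series(dendrite_id, M_amp, A_amp, M_int, A_int)

  ca_nl <- NA_real_
  ca_tbl <- NULL
  if (!is.null(linescans) && length(linescans)) {
    ca_tbl <- analyze_calcium(linescans, protocol, config, dendrite_id)
    ca_nl <- calcium_nonlinearity(ca_tbl$dfa, ca_tbl$expected,
                                  eps = config$eps)
  }

  meta <- sweeps[[1]]$meta
  result <- tibble::tibble(
    dendrite_id = dendrite_id,
    drug_condition = meta$drug_condition %||% NA_character_,
    amp_nonlinearity_pct = as.numeric(amp_nl),
    int_nonlinearity_pct = as.numeric(int_nl),
    ca_nonlinearity_pct = as.numeric(ca_nl),
    n_locations = n_loc,
    n_used = attr(amp_nl, "n_used"),
    distance_um = meta$distance_um %||% NA_real_,
    dendrite_order = meta$dendrite_order %||% NA_real_,
    diameter_um = meta$diameter_um %||% NA_real_
  )
  structure(
    list(result = result, series = series, calcium = ca_tbl),
    class = "dendrite_analysis"
  )
}

# per-k calcium quantification: artifact removal, peak delta-F/A per
# near-synchronous location count, asynchronous end-of-record reference and
# the interpolated expectation
analyze_calcium <- function(linescans, protocol, config, dendrite_id) {
  n_loc <- protocol$n_locations
  conds <- vapply(linescans, `[[`, character(1), "condition")
  ks <- vapply(linescans, `[[`, integer(1), "k_active")
  clean <- lapply(linescans, function(s) {
    remove_uncaging_artifacts(s, pulse_duration_ms = protocol$pulse_duration_ms)
  })
  dfa_of <- function(group, peak_window = NULL) {
    vals <- vapply(group, function(s) {
      delta_f_over_a(s, config$ca_baseline_window_ms, peak_window,
                     config$ca_smooth_window_ms)
    }, numeric(1))
    mean(vals)
  }
  dfa <- vapply(seq_len(n_loc), function(k) {
    grp <- clean[conds == "near_synchronous" & ks == k]
    if (!length(grp)) {
      stop(sprintf("dendrite %s: missing near-synchronous linescan for k = %d",
                   dendrite_id, k), call. = FALSE)
    }
    dfa_of(grp)
  }, numeric(1))
  async <- clean[conds == "asynchronous"]
  if (!length(async)) {
    stop("no asynchronous linescan for the calcium reference", call. = FALSE)
  }
  # reference: transient at the end of the asynchronous record, after the
  # final uncaging event, so that it encompasses all n locations
  last_on <- max(async[[1]]$onset_times_ms)
  end_ms <- length(async[[1]]$green) * async[[1]]$line_period_ms
  dfa_async_n <- dfa_of(async, peak_window = c(last_on, end_ms))
  expected <- interpolate_expected_calcium(dfa[1], dfa_async_n, n_loc)
  tibble::tibble(
    dendrite_id = dendrite_id,
    k = seq_len(n_loc),
    dfa = dfa,
    expected = expected,
    dfa_async_n = dfa_async_n
  )
}

#' @export
print.dendrite_analysis <- function(x, ...) {
  r <- x$result
  cat(sprintf("<dendrite_analysis> %s (%s)\n", r$dendrite_id,
              r$drug_condition))
  cat(sprintf("  amplitude nonlinearity: %+.1f%%\n", r$amp_nonlinearity_pct))
  cat(sprintf("  integral  nonlinearity: %+.1f%%\n", r$int_nonlinearity_pct))
  if (is.finite(r$ca_nonlinearity_pct)) {
    cat(sprintf("  calcium   nonlinearity: %+.1f%%\n", r$ca_nonlinearity_pct))
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @exportS3Method generics::glance
glance.dendrite_analysis <- function(x, ...) x$result

#' @exportS3Method generics::tidy
tidy.dendrite_analysis <- function(x, ...) x$series
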