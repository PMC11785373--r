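#' Double-exponential unitary uEPSP kernel
#'
#' Builds the waveform of a unitary uncaging-evoked EPSP as a difference of
#' exponentials, `exp(-t/tau_decay) - exp(-t/tau_rise)`, sampled on the
#' recording grid and normalized so that its maximum sample equals
#' `amplitude_mv`.  The waveform starts at 0 at `t = 0`.
#'
#' @param tau_rise_ms,tau_decay_ms Time constants, ms
#'   (`tau_decay_ms > tau_rise_ms > 0`).
#' @param amplitude_mv Peak amplitude, mV (> 0).
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param duration_ms Kernel support, ms (default 100).
#'
#' @return Numeric vector of length `round(duration_ms * fs / 1000)`.
#' @examples
#' k <- make_uepsp_kernel(1, 10, 1, 20000)
#' max(k)  # exactly 1
#' @export
make_uepsp_kernel <- function(tau_rise_ms, tau_decay_ms, amplitude_mv,
                              sampling_rate_hz, duration_ms = 100) {
  if (!(tau_rise_ms > 0) || !(tau_decay_ms > tau_rise_ms)) {
    stop("need tau_decay_ms > tau_rise_ms > 0", call. = FALSE)
  }
  if (!(amplitude_mv > 0)) stop("`amplitude_mv` must be positive", call. = FALSE)
  n <- round(duration_ms * sampling_rate_hz / 1000)
  t <- (seq_len(n) - 1) / sampling_rate_hz * 1000
  w <- exp(-t / tau_decay_ms) - exp(-t / tau_rise_ms)
  amplitude_mv * (w / max(w))
}

# closed-form time of the kernel maximum (ms); grid argmax lies within one
# sample period of this
uepsp_peak_time_ms <- function(tau_rise_ms, tau_decay_ms) {
  tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms)
}

#' Delay a sampled trace by a (possibly fractional) number of samples
#'
#' Shifts a trace later in time by `delay_ms` using linear interpolation for
#' the fractional part of the delay; the vacated leading samples are zero and
#' the trailing samples beyond the original support are dropped.  This is the
#' single shift primitive used both when constructing arithmetic-sum traces
#' and when the synthetic generator places near-synchronous events, so the
#' two stay numerically consistent.
#'
#' @param x Numeric vector.
#' @param delay_ms Non-negative delay, ms.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @return Numeric vector, same length as `x`.
#' @export
shift_trace <- function(x, delay_ms, sampling_rate_hz) {
  if (delay_ms < 0) stop("`delay_ms` must be >= 0", call. = FALSE)
  d <- delay_ms * sampling_rate_hz / 1000
  i0 <- floor(d)
  f <- d - i0
  n <- length(x)
  if (i0 >= n) return(numeric(n))
  a <- c(rep(0, i0), x)[seq_len(n)]        # delayed by i0 samples
  if (f == 0) return(a)
  b <- c(rep(0, i0 + 1), x)[seq_len(n)]    # delayed by i0 + 1 samples
  (1 - f) * a + f * b
}

#' Dendritic input-output transfer function
#'
#' Maps a linear dendritic drive (the staggered sum of unitary uEPSPs, mV)
#' to the observed depolarization: a sigmoid boost of magnitude `gain_G`
#' centred at `threshold_theta_mv` composed with an exponential saturation
#' at `v_sat_mv`.  With `gain_G = 0` and infinite `v_sat_mv` this is the
#' identity, i.e. perfectly linear integration.
#'
#' @param drive_mv Numeric vector of linear drive, mV.
#' @param params A [gain_params()] object.
#' @return Numeric vector of observed depolarization, mV.
#' @export
dendritic_transfer <- function(drive_mv, params) {
  L <- drive_mv
  y <- L + params$gain_G * L *
    stats::plogis((L - params$threshold_theta_mv) / params$slope_kappa_mv)
  if (is.finite(params$v_sat_mv)) {
    y <- params$v_sat_mv * (1 - exp(-y / params$v_sat_mv))
  }
  y
}

# Noise-free depolarization signal for one sweep.  Unitary kernels are
# truncated `baseline_guard_ms` short of the asynchronous inter-onset period
# so that every event is preceded by a true-zero baseline window; the same
# truncated kernels, placed with `shift_trace()`, define the
# near-synchronous drive.  Returns the signal (baseline-relative, mV), the
# exact onset times and the index of the first onset.
synthetic_signal <- function(protocol, params,
                             condition = c("asynchronous", "near_synchronous"),
                             k_locations = protocol$n_locations,
                             baseline_guard_ms = 5,
                             tail_ms = 60) {
  condition <- match.arg(condition)
  fs <- protocol$sampling_rate_hz
  n_loc <- protocol$n_locations
  amps <- rep_len(params$unitary_amplitudes_mv, n_loc)
  seg <- protocol_segment_samples(protocol)
  guard <- round(baseline_guard_ms * fs / 1000)
  klen <- seg - guard
  if (klen < 2) stop("sweep shorter than required span", call. = FALSE)
  kern <- make_uepsp_kernel(params$tau_rise_ms, params$tau_decay_ms, 1, fs,
                            duration_ms = klen / fs * 1000)
  kern <- kern[seq_len(klen)]
  first_idx <- round(protocol$first_onset_ms * fs / 1000)

  if (condition == "asynchronous") {
    spacing <- async_spacing_ms(protocol) * fs / 1000
    onset_idx <- first_idx + round((seq_len(n_loc) - 1) * spacing)
    total <- max(onset_idx) + seg + round(tail_ms * fs / 1000)
    sig <- numeric(total)
    for (j in seq_len(n_loc)) {
      sig[onset_idx[j] + seq_len(klen)] <-
        sig[onset_idx[j] + seq_len(klen)] + amps[j] * kern
    }
    onsets_ms <- onset_idx * 1000 / fs
  } else {
    if (k_locations < 1 || k_locations > n_loc) {
      stop("`k_locations` out of range", call. = FALSE)
    }
    span <- seg + round(((n_loc - 1) * protocol$onset_stagger_ms + tail_ms) *
                          fs / 1000)
    total <- first_idx + span
    buf <- numeric(span)
    for (j in seq_len(k_locations)) {
      ev <- shift_trace(c(amps[j] * kern, numeric(span - klen)),
                        (j - 1) * protocol$onset_stagger_ms, fs)
      buf <- buf + ev
    }
    sig <- c(numeric(first_idx), buf)
    onsets_ms <- first_idx * 1000 / fs +
      (seq_len(k_locations) - 1) * protocol$onset_stagger_ms
  }
  list(signal = sig, onset_times_ms = onsets_ms, first_idx = first_idx)
}

# add recording noise, optional action-potential contamination and the
# resting potential; assumes the RNG state has been set by the caller
finish_sweep <- function(sig, params, protocol, condition, k_active,
                         onsets_ms, meta, seed) {
  if (!is.null(seed)) set.seed(seed)
  obs <- dendritic_transfer(sig$signal, params)
  contaminated <- params$ap_probability > 0 &&
    stats::runif(1) < params$ap_probability
  if (contaminated) {
    fs <- protocol$sampling_rate_hz
    # stereotyped 60 mV spike, 2 ms wide: 0.5 ms upstroke, 1.5 ms decay
    up <- round(0.5 * fs / 1000); dn <- round(1.5 * fs / 1000)
    spike <- 60 * c(seq(0, 1, length.out = up + 1)[-1],
                    seq(1, 0, length.out = dn + 1)[-1])
    peak <- which.max(sig$signal)
    idx <- peak - up + seq_along(spike)
    keep <- idx >= 1 & idx <= length(obs)
    obs[idx[keep]] <- obs[idx[keep]] + spike[keep]
  }
  if (params$noise_sd_mv > 0) {
    obs <- obs + stats::rnorm(length(obs), 0, params$noise_sd_mv)
  }
  voltage_sweep(obs + params$v_rest_mv, protocol$sampling_rate_hz,
                condition = condition, onset_times_ms = onsets_ms,
                k_active = k_active,
                meta = c(meta, list(ap_contaminated = contaminated)))
}

#' Simulate an asynchronous ("separate responses") sweep
#'
#' One uncaging pulse per location with the long asynchronous gap, so each
#' unitary uEPSP is recorded in isolation.  Onsets are placed on the sample
#' grid; each unitary response is passed through the dendritic transfer
#' function (events are isolated, so this equals applying the transfer to
#' the whole drive), and Gaussian noise and the resting potential are added.
#'
#' @param protocol An [uncaging_protocol()].
#' @param params A [gain_params()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param meta Metadata list stored on the sweep.
#' @return A [voltage_sweep()].
#' @export
simulate_asynchronous_sweep <- function(protocol, params,
                                        seed = params$seed, meta = list()) {
  sig <- synthetic_signal(protocol, params, "asynchronous")
  finish_sweep(sig, params, protocol, "asynchronous", NA_integer_,
               sig$onset_times_ms, meta, seed)
}

#' Simulate a near-synchronous sweep with k active locations
#'
#' The first `k_locations` unitary kernels are staggered by the protocol's
#' onset-to-onset spacing and summed into a linear drive, which is passed
#' through the dendritic transfer function ([dendritic_transfer()]); noise
#' and the resting potential are then added.
#'
#' @inheritParams simulate_asynchronous_sweep
#' @param k_locations Number of co-active locations, `1..n_locations`.
#' @return A [voltage_sweep()].
#' @export
simulate_near_synchronous_sweep <- function(protocol, params, k_locations,
                                            seed = params$seed, meta = list()) {
  sig <- synthetic_signal(protocol, params, "near_synchronous", k_locations)
  finish_sweep(sig, params, protocol, "near_synchronous",
               as.integer(k_locations), sig$onset_times_ms, meta, seed)
}

#' Simulate a two-channel calcium linescan
#'
#' Integrates a single calcium pool driven by the supplied depolarization
#' (`dc/dt = -c/tau_ca + influx * max(V - v_threshold, 0) * g(c)`, with
#' `g(c) = store_gain` above `store_threshold`), renders green fluorescence
#' as `baseline_green * (1 + k_f * c)` and red as a flat reference, adds
#' uncaging light artifacts on both channels at pulse times, and Gaussian
#' noise.  Lines hit by an artifact are recorded in the artifact mask.
#'
#' @param protocol An [uncaging_protocol()].
#' @param params A [calcium_params()].
#' @param voltage_mv Baseline-relative depolarization driving the influx,
#'   mV, sampled at `sampling_rate_hz`; must cover the protocol span.
#' @param sampling_rate_hz Sampling rate of `voltage_mv`, Hz.
#' @param onset_times_ms Uncaging pulse onsets, ms.
#' @param condition,k_active As in [linescan()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param meta Metadata list.
#' @return A [linescan()].
#' @export
simulate_linescan <- function(protocol, params, voltage_mv, sampling_rate_hz,
                              onset_times_ms,
                              condition = c("asynchronous", "near_synchronous"),
                              k_active = NA_integer_,
                              seed = params$seed, meta = list()) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  dur_ms <- length(voltage_mv) / sampling_rate_hz * 1000
  if (length(onset_times_ms) &&
      max(onset_times_ms) + protocol$pulse_duration_ms > dur_ms) {
    stop("voltage trace does not cover the protocol span", call. = FALSE)
  }
  dt <- 1000 / sampling_rate_hz
  drive <- params$influx_per_mv * pmax(voltage_mv - params$v_threshold_mv, 0) * dt
  decay <- dt / params$tau_ca_ms
  n <- length(voltage_mv)
  conc <- numeric(n)
  ci <- 0
  for (i in seq_len(n)) {
    g <- if (ci > params$store_threshold) params$store_gain else 1
    ci <- ci + drive[i] * g - ci * decay
    conc[i] <- ci
  }
  n_lines <- floor(dur_ms / params$line_period_ms)
  t_lines <- (seq_len(n_lines) - 0.5) * params$line_period_ms
  c_lines <- stats::approx((seq_len(n) - 1) * dt, conc, xout = t_lines,
                           rule = 2)$y
  green <- params$baseline_green * (1 + params$k_f * c_lines)
  red <- rep(params$baseline_red, n_lines)
  mask <- rep(FALSE, n_lines)
  for (on in onset_times_ms) {
    hit <- which(t_lines + params$line_period_ms / 2 > on &
                   t_lines - params$line_period_ms / 2 <
                     on + protocol$pulse_duration_ms)
    mask[hit] <- TRUE
  }
  green[mask] <- green[mask] + params$artifact_amplitude
  red[mask] <- red[mask] + params$artifact_amplitude
  if (params$noise_sd_green > 0) {
    green <- green + stats::rnorm(n_lines, 0, params$noise_sd_green)
  }
  if (params$noise_sd_red > 0) {
    red <- red + stats::rnorm(n_lines, 0, params$noise_sd_red)
  }
  linescan(green, red, params$line_period_ms, onset_times_ms,
           artifact_mask = mask, condition = condition,
           k_active = k_active, meta = meta)
}

#' Generate a complete synthetic uncaging experiment
#'
#' Emits `n_cycles` repeats of the full stimulation protocol for one
#' dendrite -- one asynchronous sweep plus near-synchronous sweeps for
#' `k = 1..n_locations` per cycle, with matching linescans when
#' `calcium_params` is supplied -- together with a noiseless twin of the same
#' experiment.  Ground-truth percent-nonlinearity values are computed by
#' running the standard measurement pipeline ([analyze_dendrite()]) on the
#' noiseless twin, so every downstream stage can be validated against known
#' truth.
#'
#' Reproducibility: the top-level seed in `gain_params$seed` deterministically
#' derives one sub-seed per sweep and linescan, so regeneration with the same
#' parameters is bitwise identical.
#'
#' @param protocol An [uncaging_protocol()].
#' @param params A [gain_params()].
#' @param ca_params A [calcium_params()] or `NULL` to skip linescans.
#' @param n_cycles Number of stimulation cycles (>= 1, default 3).
#' @param dendrite_id Identifier stored on every record.
#' @param drug_condition Condition label stored on every record.
#' @param ground_truth Compute the noiseless ground truth (default `TRUE`).
#'
#' @return An object of class `uncaging_experiment` with elements
#'   `protocol`, `sweeps`, `linescans`, `noiseless_sweeps`,
#'   `noiseless_linescans`, `ground_truth`, and the generating parameters.
#' @export
generate_experiment <- function(protocol, params, ca_params = NULL,
                                n_cycles = 3, dendrite_id = "dendrite_1",
                                drug_condition = "control",
                                ground_truth = TRUE) {
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  n_loc <- protocol$n_locations
  set.seed(params$seed)
  per_cycle <- 1 + n_loc
  seeds <- matrix(sample.int(.Machine$integer.max, 2 * n_cycles * per_cycle),
                  nrow = 2)  # row 1: sweeps, row 2: linescans

  base_meta <- list(dendrite_id = dendrite_id, drug_condition = drug_condition)
  # noise-free drive signals are identical across cycles; compute once
  sig_async <- synthetic_signal(protocol, params, "asynchronous")
  sig_ns <- lapply(seq_len(n_loc), function(k) {
    synthetic_signal(protocol, params, "near_synchronous", k)
  })
  transferred <- function(sig) dendritic_transfer(sig$signal, params)

  sweeps <- list()
  linescans <- if (is.null(ca_params)) NULL else list()
  s <- 0
  for (cyc in seq_len(n_cycles)) {
    meta <- c(base_meta, list(cycle = cyc))
    s <- s + 1
    sweeps[[length(sweeps) + 1]] <-
      finish_sweep(sig_async, params, protocol, "asynchronous", NA_integer_,
                   sig_async$onset_times_ms, meta, seeds[1, s])
    if (!is.null(ca_params)) {
      linescans[[length(linescans) + 1]] <-
        simulate_linescan(protocol, ca_params, transferred(sig_async),
                          protocol$sampling_rate_hz, sig_async$onset_times_ms,
                          "asynchronous", NA_integer_, seeds[2, s], meta)
    }
    for (k in seq_len(n_loc)) {
      s <- s + 1
      sweeps[[length(sweeps) + 1]] <-
        finish_sweep(sig_ns[[k]], params, protocol, "near_synchronous",
                     as.integer(k), sig_ns[[k]]$onset_times_ms, meta,
                     seeds[1, s])
      if (!is.null(ca_params)) {
        linescans[[length(linescans) + 1]] <-
          simulate_linescan(protocol, ca_params, transferred(sig_ns[[k]]),
                            protocol$sampling_rate_hz,
                            sig_ns[[k]]$onset_times_ms,
                            "near_synchronous", as.integer(k), seeds[2, s],
                            meta)
      }
    }
  }

  # noiseless twin: one cycle, no noise, no spikes, no fluorescence noise
  params0 <- params
  params0$noise_sd_mv <- 0
  params0$ap_probability <- 0
  ca0 <- ca_params
  if (!is.null(ca0)) {
    ca0$noise_sd_green <- 0
    ca0$noise_sd_red <- 0
  }
  meta0 <- c(base_meta, list(cycle = 1L))
  noiseless <- list(finish_sweep(sig_async, params0, protocol, "asynchronous",
                                 NA_integer_, sig_async$onset_times_ms,
                                 meta0, NULL))
  noiseless_ls <- if (is.null(ca0)) NULL else list(
    simulate_linescan(protocol, ca0, transferred(sig_async),
                      protocol$sampling_rate_hz, sig_async$onset_times_ms,
                      "asynchronous", NA_integer_, NULL, meta0))
  for (k in seq_len(n_loc)) {
    noiseless[[length(noiseless) + 1]] <-
      finish_sweep(sig_ns[[k]], params0, protocol, "near_synchronous",
                   as.integer(k), sig_ns[[k]]$onset_times_ms, meta0, NULL)
    if (!is.null(ca0)) {
      noiseless_ls[[length(noiseless_ls) + 1]] <-
        simulate_linescan(protocol, ca0, transferred(sig_ns[[k]]),
                          protocol$sampling_rate_hz, sig_ns[[k]]$onset_times_ms,
                          "near_synchronous", as.integer(k), NULL, meta0)
    }
  }

  exp <- structure(
    list(
      protocol = protocol,
      gain_params = params,
      calcium_params = ca_params,
      n_cycles = as.integer(n_cycles),
      dendrite_id = dendrite_id,
      drug_condition = drug_condition,
      sweeps = sweeps,
      linescans = linescans,
      noiseless_sweeps = noiseless,
      noiseless_linescans = noiseless_ls,
      ground_truth = NULL
    ),
    class = "uncaging_experiment"
  )
  if (ground_truth) {
    gt <- analyze_dendrite(noiseless, noiseless_ls, protocol,
                           dendrite_id = paste0(dendrite_id, "_truth"))
    exp$ground_truth <- list(
      amp_nonlinearity_pct = gt$result$amp_nonlinearity_pct,
      int_nonlinearity_pct = gt$result$int_nonlinearity_pct,
      ca_nonlinearity_pct = gt$result$ca_nonlinearity_pct,
      series = gt$series
    )
  }
  exp
}

#' @export
print.uncaging_experiment <- function(x, ...) {
  cat(sprintf("<uncaging_experiment> %s: %d cycles, %d sweeps%s\n",
              x$dendrite_id, x$n_cycles, length(x$sweeps),
              if (!is.null(x$linescans)) {
                sprintf(", %d linescans", length(x$linescans))
              } else ""))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: amplitude %+.1f%%, integral %+.1f%%%s\n",
                x$ground_truth$amp_nonlinearity_pct,
                x$ground_truth$int_nonlinearity_pct,
                if (is.finite(x$ground_truth$ca_nonlinearity_pct %||% NA)) {
                  sprintf(", calcium %+.1f%%", x$ground_truth$ca_nonlinearity_pct)
                } else ""))
  }
  invisible(x)
}
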