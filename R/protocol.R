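#' Uncaging protocol definition
#'
#' Describes the timing of a multi-site two-photon glutamate uncaging
#' experiment: the number of dendritic locations, the light-pulse duration,
#' and the inter-pulse gaps used in the two stimulation conditions.  In the
#' asynchronous ("separate responses") condition one location is stimulated
#' at a time with a long gap so that unitary uEPSPs are isolated; in the
#' near-synchronous condition pulses follow each other with a sub-millisecond
#' gap so that responses summate.  The onset-to-onset stagger used when
#' constructing arithmetic-sum traces equals pulse duration plus the
#' near-synchronous gap.
#'
#' @param n_locations Number of uncaging locations (default 12).
#' @param pulse_duration_ms Uncaging light-pulse duration in ms (default 0.5).
#' @param async_gap_ms Gap between pulses in the asynchronous condition, ms
#'   (default 100.32, i.e. 100.82 ms onset-to-onset).
#' @param sync_gap_ms Gap between pulses in the near-synchronous condition,
#'   ms (default 0.32, i.e. 0.82 ms onset-to-onset).
#' @param onset_stagger_ms Onset-to-onset spacing used for arithmetic
#'   summation, ms.  Defaults to `pulse_duration_ms + sync_gap_ms`.
#' @param sampling_rate_hz Voltage sampling rate in Hz (default 20000).
#' @param first_onset_ms Time of the first uncaging pulse within a sweep, ms
#'   (default 100, leaving a pre-stimulus baseline).
#'
#' @return An object of class `uncaging_protocol`.
#' @examples
#' p <- uncaging_protocol()
#' p$onset_stagger_ms  # 0.82
#' @export
uncaging_protocol <- function(n_locations = 12,
                              pulse_duration_ms = 0.5,
                              async_gap_ms = 100.32,
                              sync_gap_ms = 0.32,
                              onset_stagger_ms = pulse_duration_ms + sync_gap_ms,
                              sampling_rate_hz = 20000,
                              first_onset_ms = 100) {
  if (n_locations < 2) stop("`n_locations` must be >= 2", call. = FALSE)
  durs <- c(pulse_duration_ms, async_gap_ms, sync_gap_ms, onset_stagger_ms,
            sampling_rate_hz, first_onset_ms)
  if (any(!is.finite(durs)) || any(durs[1:5] <= 0) || first_onset_ms < 0) {
    stop("protocol durations and rates must be positive", call. = FALSE)
  }
  structure(
    list(
      n_locations = as.integer(n_locations),
      pulse_duration_ms = as.numeric(pulse_duration_ms),
      async_gap_ms = as.numeric(async_gap_ms),
      sync_gap_ms = as.numeric(sync_gap_ms),
      onset_stagger_ms = as.numeric(onset_stagger_ms),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      first_onset_ms = as.numeric(first_onset_ms)
    ),
    class = "uncaging_protocol"
  )
}

#' @export
print.uncaging_protocol <- function(x, ...) {
  cat("<uncaging_protocol>\n")
  cat(sprintf("  %d locations, %.2f ms pulses @ %g Hz sampling\n",
              x$n_locations, x$pulse_duration_ms, x$sampling_rate_hz))
  cat(sprintf("  asynchronous gap %.2f ms, near-synchronous gap %.2f ms\n",
              x$async_gap_ms, x$sync_gap_ms))
  cat(sprintf("  arithmetic-sum stagger %.2f ms, first onset %.2f ms\n",
              x$onset_stagger_ms, x$first_onset_ms))
  invisible(x)
}

# onset-to-onset spacing (ms) of the asynchronous condition
async_spacing_ms <- function(protocol) {
  protocol$pulse_duration_ms + protocol$async_gap_ms
}

# length, in samples, of the analysis segment associated with one unitary
# response: one asynchronous inter-onset period rounded down to the grid
protocol_segment_samples <- function(protocol) {
  floor(async_spacing_ms(protocol) * protocol$sampling_rate_hz / 1000)
}

#' Synthetic voltage-response model parameters
#'
#' Parameters of the mechanistic stand-in used to generate somatic voltage
#' responses: unitary uEPSPs are double-exponential kernels; the summed
#' dendritic drive is passed through a sigmoid boost (a voltage-dependent
#' amplification mimicking NMDA-receptor recruitment) composed with an
#' exponential saturation (mimicking the loss of synaptic driving force as
#' the local membrane potential approaches the reversal potential).
#'
#' The observed depolarization for a linear drive `L` is
#' `S(L + G * L * logistic((L - theta) / kappa))` with
#' `S(x) = v_sat * (1 - exp(-x / v_sat))` (`S` is the identity when
#' `v_sat_mv` is infinite).  `gain_G = 0` with infinite `v_sat_mv` therefore
#' yields exactly linear summation.
#'
#' @param unitary_amplitudes_mv Peak amplitude of the unitary uEPSP at each
#'   location, mV.  Recycled to the protocol's location count.
#' @param tau_rise_ms,tau_decay_ms Kernel time constants, ms
#'   (`tau_decay_ms > tau_rise_ms > 0`).
#' @param gain_G Dimensionless magnitude of the sigmoid boost (>= 0).
#' @param threshold_theta_mv Half-activation of the boost, mV.
#' @param slope_kappa_mv Slope factor of the boost sigmoid, mV.
#' @param v_sat_mv Saturation ceiling, mV; `Inf` disables saturation.
#' @param noise_sd_mv Standard deviation of additive Gaussian recording
#'   noise, mV per sample.
#' @param ap_probability Per-sweep probability of injecting a stereotyped
#'   action-potential contamination (60 mV, 2 ms triangular spike at the
#'   response peak).
#' @param v_rest_mv Resting membrane potential added to every sweep, mV.
#' @param seed Integer seed for the generator.
#'
#' @return An object of class `gain_params`.
#' @export
gain_params <- function(unitary_amplitudes_mv = c(1.2, 0.8, 1.0, 1.5, 0.7, 1.1,
                                                  0.9, 1.3, 0.6, 1.0, 1.4, 0.8),
                        tau_rise_ms = 1,
                        tau_decay_ms = 20,
                        gain_G = 2,
                        threshold_theta_mv = 4,
                        slope_kappa_mv = 1.5,
                        v_sat_mv = 40,
                        noise_sd_mv = 0.1,
                        ap_probability = 0,
                        v_rest_mv = -65,
                        seed = 1L) {
  if (tau_rise_ms <= 0 || tau_decay_ms <= 0 || tau_decay_ms <= tau_rise_ms) {
    stop("need tau_decay_ms > tau_rise_ms > 0", call. = FALSE)
  }
  if (gain_G < 0) stop("`gain_G` must be >= 0", call. = FALSE)
  if (!(v_sat_mv > 0)) stop("`v_sat_mv` must be positive (or Inf)", call. = FALSE)
  if (ap_probability < 0 || ap_probability > 1) {
    stop("`ap_probability` must be in [0, 1]", call. = FALSE)
  }
  if (any(unitary_amplitudes_mv <= 0)) {
    stop("unitary amplitudes must be positive", call. = FALSE)
  }
  if (noise_sd_mv < 0) stop("`noise_sd_mv` must be >= 0", call. = FALSE)
  structure(
    list(
      unitary_amplitudes_mv = unitary_amplitudes_mv,
      tau_rise_ms = tau_rise_ms,
      tau_decay_ms = tau_decay_ms,
      gain_G = gain_G,
      threshold_theta_mv = threshold_theta_mv,
      slope_kappa_mv = slope_kappa_mv,
      v_sat_mv = v_sat_mv,
      noise_sd_mv = noise_sd_mv,
      ap_probability = ap_probability,
      v_rest_mv = v_rest_mv,
      seed = as.integer(seed)
    ),
    class = "gain_params"
  )
}

#' Synthetic calcium-linescan model parameters
#'
#' Parameters of the calcium stand-in: a single calcium pool driven by
#' supra-threshold depolarization, with first-order decay and a
#' multiplicative amplification once the pool exceeds `store_threshold`
#' (mimicking calcium-induced calcium release from intracellular stores,
#' which produces the abrupt jump of the fluorescence transient with the
#' number of co-active locations).  Fluorescence is reported on two
#' channels: a calcium-sensitive green channel (Fluo-4-like) and a
#' calcium-insensitive red reference (Alexa-594-like).
#'
#' The pool evolves as
#' `dc/dt = -c/tau_ca + influx_per_mv * max(V - v_threshold, 0) * g(c)`
#' with `g(c) = store_gain` when `c > store_threshold` and 1 otherwise.
#'
#' @param influx_per_mv Influx scale, pool units per mV per ms.
#' @param tau_ca_ms Calcium decay time constant, ms.
#' @param v_threshold_mv Depolarization threshold for influx, mV.
#' @param store_gain Multiplicative amplification above `store_threshold`
#'   (>= 1; 1 disables store release).
#' @param store_threshold Pool level above which `store_gain` applies.
#' @param baseline_green,baseline_red Baseline fluorescence, au (> 0).
#' @param k_f Fractional green-fluorescence change per pool unit.
#' @param artifact_amplitude Height of the uncaging light artifact added to
#'   both channels at pulse times, au.
#' @param noise_sd_green,noise_sd_red Gaussian noise SD per line, au.
#' @param line_period_ms Linescan period (time per line), ms.
#' @param seed Integer seed used when a linescan is simulated standalone.
#'
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(influx_per_mv = 0.03,
                           tau_ca_ms = 80,
                           v_threshold_mv = 0.5,
                           store_gain = 3,
                           store_threshold = 3.5,
                           baseline_green = 100,
                           baseline_red = 200,
                           k_f = 0.5,
                           artifact_amplitude = 500,
                           noise_sd_green = 1.5,
                           noise_sd_red = 1.5,
                           line_period_ms = 2,
                           seed = 1L) {
  if (tau_ca_ms <= 0) stop("`tau_ca_ms` must be positive", call. = FALSE)
  if (baseline_green <= 0 || baseline_red <= 0) {
    stop("baseline fluorescence must be positive", call. = FALSE)
  }
  if (store_gain < 1) stop("`store_gain` must be >= 1", call. = FALSE)
  if (line_period_ms <= 0) stop("`line_period_ms` must be positive", call. = FALSE)
  structure(
    list(
      influx_per_mv = influx_per_mv,
      tau_ca_ms = tau_ca_ms,
      v_threshold_mv = v_threshold_mv,
      store_gain = store_gain,
      store_threshold = store_threshold,
      baseline_green = baseline_green,
      baseline_red = baseline_red,
      k_f = k_f,
      artifact_amplitude = artifact_amplitude,
      noise_sd_green = noise_sd_green,
      noise_sd_red = noise_sd_red,
      line_period_ms = line_period_ms,
      seed = as.integer(seed)
    ),
    class = "calcium_params"
  )
}
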