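test_that("unitary extraction recovers identical segments and re-baselines residual decay", {
  p <- default_protocol()
  gp <- gain_params(unitary_amplitudes_mv = rep(1, 12), gain_G = 0,
                    v_sat_mv = Inf, noise_sd_mv = 0)
  fs <- p$sampling_rate_hz
  sw <- simulate_asynchronous_sweep(p, gp)
  sweep0 <- voltage_sweep(sw$samples - gp$v_rest_mv, fs, "asynchronous",
                          sw$onset_times_ms)
  un <- extract_unitaries(sweep0, n_locations = 12)
  expect_length(un, 12)
  for (j in 2:12) expect_equal(un[[j]]$segment, un[[1]]$segment)

  # residual decay from a previous event is removed to < 2% of the peak:
  # build a trace with full (untruncated) exponential tails by hand
  tau_d <- 20
  kern <- make_uepsp_kernel(1, tau_d, 2, fs, duration_ms = 400)
  spacing <- 100.82
  n <- round(420 * fs / 1000)
  v <- numeric(n)
  on_idx <- round(c(10, 10 + spacing) * fs / 1000)
  for (i0 in on_idx) {
    idx <- i0 + seq_along(kern)
    keep <- idx <= n
    v[idx[keep]] <- v[idx[keep]] + kern[keep]
  }
  sw2 <- voltage_sweep(v, fs, "asynchronous", on_idx * 1000 / fs)
  un2 <- extract_unitaries(sw2, n_locations = 2, segment_ms = 100)
  # the second segment sits on a tail of amplitude ~ 2*exp(-100.82/20);
  # re-baselining must cut the discrepancy below 2% of the 2 mV peak
  expect_lt(max(abs(un2[[2]]$segment - un2[[1]]$segment)), 0.02 * 2)
  # and the uncorrected tail really was above that bound
  expect_gt(2 * exp(-spacing / tau_d), 0.002)

  # wrong onset count errors
  expect_error(extract_unitaries(sweep0, n_locations = 12,
                                 onset_times_ms = sw$onset_times_ms[1:11]),
               "expected 12 onsets")
  # onset too close to the end errors
  sw3 <- voltage_sweep(v[1:3000], fs, "asynchronous", c(10, 120))
  expect_error(extract_unitaries(sw3, segment_ms = 100), "too close")
})

test_that("arithmetic summation staggers, preserves k=1, and is exactly additive in the integral", {
  fs <- 20000
  # two near-impulse segments
  seg <- numeric(400); seg[5] <- 1
  mk_un <- function(s, j) structure(
    list(segment = s, location_index = j, sampling_rate_hz = fs,
         duration_ms = length(s) / fs * 1000), class = "unitary_response")
  un <- list(mk_un(seg, 1), mk_un(seg, 2))
  expect_identical(arithmetic_sum(un, 1), seg)
  s2 <- arithmetic_sum(un, 2, onset_stagger_ms = 0.82)
  # two distinct peaks separated by 0.82 ms (16.4 samples -> 16 or 17 apart)
  top <- sort(which(s2 > 0.5))
  expect_equal(diff(range(top)), 17, tolerance = 1)

  # integral additivity on smooth kernels, within interpolation error
  p <- default_protocol()
  kern1 <- make_uepsp_kernel(1, 20, 1.0, fs, 95)
  kern2 <- make_uepsp_kernel(1, 20, 1.5, fs, 95)
  pad <- function(x) c(x, numeric(2016 - length(x)))
  un2 <- list(mk_un(pad(kern1), 1), mk_un(pad(kern2), 2))
  tot <- arithmetic_sum(un2, 2, 0.82)
  int_sum <- measure_integral(tot, fs, 100)
  parts <- measure_integral(pad(kern1), fs, 100) +
    measure_integral(shift_trace(pad(kern2), 0.82, fs), fs, 100)
  expect_equal(int_sum, parts, tolerance = 1e-6)
  expect_error(arithmetic_sum(un2, 3), "out of range")
})

test_that("peak measurement matches rectangles, kernels and the zero trace", {
  fs <- 20000
  rect <- c(numeric(100), rep(1, 200), numeric(1900))  # 1 mV for 10 ms
  expect_equal(measure_peak(rect, fs), 1.0)
  expect_equal(measure_peak(numeric(2100), fs), 0.0)
  # summed double exponentials: compare against a fine-grid numeric argmax
  k1 <- make_uepsp_kernel(1, 20, 1, fs, 100)
  tot <- k1 + shift_trace(k1, 0.82, fs)
  tfine <- seq(0, 99, by = 1e-3)
  u <- function(t) {
    w <- ifelse(t < 0, 0, exp(-t / 20) - exp(-t / 1))
    w / max(exp(-(1 * 20 / 19 * log(20)) / 20) - exp(-(1 * 20 / 19 * log(20)) / 1))
  }
  oracle <- max(u(tfine) + u(tfine - 0.82))
  expect_equal(measure_peak(tot, fs), oracle, tolerance = 1e-3)
  expect_error(measure_peak(rect, fs, window_ms = c(500, 600)), "window")
})

test_that("integral measurement matches closed forms", {
  fs <- 20000
  rect <- c(0, rep(1, 200), numeric(1900))  # 1 mV x 10 ms pulse
  expect_equal(measure_integral(rect, fs, 100), 10, tolerance = 1e-9)
  expect_equal(measure_integral(numeric(2100), fs, 100), 0.0)
  # single exponential a*exp(-t/tau): integral over 100 ms = a*tau*(1-e^-5)
  tau <- 20; a <- 2
  t <- (seq_len(2101) - 1) / fs * 1000
  expo <- a * exp(-t / tau)
  expect_equal(measure_integral(expo, fs, 100), a * tau * (1 - exp(-5)),
               tolerance = 1e-3)
  expect_error(measure_integral(rect[1:100], fs, 100), "horizon")
})

test_that("min-max scaling follows the reference-extrema convention", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_scale(c(3, 5, 7), c(2, 4, 6)), c(0.25, 0.75, 1.25))
  expect_error(minmax_scale(c(1, 2), c(5, 5, 5)), "degenerate")
  # affine invariance: scaling both series by a*x + b leaves z unchanged
  x <- c(3, 5, 7); ref <- c(2, 4, 6)
  expect_equal(minmax_scale(2.5 * x + 1, 2.5 * ref + 1),
               minmax_scale(x, ref))
  # the reference itself always spans [0, 1]
  set.seed(8)
  for (i in 1:20) {
    r <- rnorm(12)
    expect_equal(range(minmax_scale(r)), c(0, 1))
  }
})

test_that("peak of a sum never exceeds the sum of unitary peaks", {
  fs <- 20000
  set.seed(12)
  for (i in 1:10) {
    segs <- lapply(1:5, function(j) {
      make_uepsp_kernel(runif(1, 0.5, 2), runif(1, 10, 30),
                        runif(1, 0.5, 2), fs, 95)
    })
    un <- lapply(seq_along(segs), function(j) structure(
      list(segment = c(segs[[j]], numeric(200)), location_index = j,
           sampling_rate_hz = fs, duration_ms = 100),
      class = "unitary_response"))
    tot <- arithmetic_sum(un, 5, 0.82)
    expect_lte(max(tot),
               sum(vapply(un, function(u) max(u$segment), numeric(1))) + 1e-12)
  }
})
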