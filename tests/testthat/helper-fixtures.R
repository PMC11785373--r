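# Shared fixtures for the test suite.  All data are generated in code; the
# small protocol keeps sweeps short so tests stay fast.

default_protocol <- function(...) uncaging_protocol(...)

# a linear, noiseless parameter set: the pipeline must recover exactly 0%
linear_params <- function(noise = 0, seed = 1L, ...) {
  gain_params(gain_G = 0, v_sat_mv = Inf, noise_sd_mv = noise,
              seed = seed, ...)
}

# a strongly supralinear parameter set
boosted_params <- function(noise = 0, seed = 1L, ...) {
  gain_params(noise_sd_mv = noise, seed = seed, ...)
}

# brute-force transcription of the nonlinearity equation, kept deliberately
# naive (explicit loop) so it is independent of the vectorized implementation
brute_force_nonlinearity <- function(M, A) {
  n <- length(M)
  acc <- 0
  for (i in 2:n) acc <- acc + (M[i] / A[i] - 1)
  acc / (n - 1) * 100
}

# independent BCa transcription (textbook formulas) used to cross-check the
# package implementation on a shared set of bootstrap replicates
reference_bca <- function(x, boot_stats, alpha = 0.05) {
  theta <- mean(x)
  B <- length(boot_stats)
  p0 <- sum(boot_stats < theta) / B
  p0 <- min(max(p0, 1 / (B + 1)), B / (B + 1))
  z0 <- qnorm(p0)
  m <- length(x)
  jack <- vapply(seq_len(m), function(i) mean(x[-i]), numeric(1))
  u <- mean(jack) - jack
  a <- sum(u^3) / (6 * sum(u^2)^1.5)
  zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  quantile(boot_stats, adj, names = FALSE, type = 7)
}
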