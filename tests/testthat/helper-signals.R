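# Shared fixtures: all synthetic, built in code at test time.

FS <- 10000
BIN_HZ <- FS / 1024   # 9.765625 Hz frequency resolution at default window

# A recording whose channels are pure sinusoids (zero-mean, so unaffected by
# the AC-coupling of the analysis band).
sine_recording <- function(n = 10240, fs = FS,
                           amp = c(fx = 172.3, fy = 67.3, fz = 115.1,
                                   v = 98.1),
                           freq = 133.5, bee_id = "sine", phase = 0) {
  t <- (seq_len(n) - 1) / fs
  s <- sin(2 * pi * freq * t + phase)
  buzz_recording(amp[["fx"]] * s, amp[["fy"]] * s, amp[["fz"]] * s,
                 amp[["v"]] * s, sample_rate = fs, bee_id = bee_id)
}

# Interior index range of a vector, trimming a fraction at each end; used to
# measure amplitudes away from record-edge filter transients.
interior <- function(n, trim = 0.1) {
  lo <- max(1L, ceiling(n * trim))
  lo:(n - lo + 1L)
}

# Deterministic quiet generator settings: single harmonic on a bin-centered
# stationary fundamental, no noise, no modulation.
quiet_params <- function(f0 = 13 * BIN_HZ, amp = 90, seed = 1, ...) {
  buzz_params(duration_s = 2, f0_mean_hz = f0, f0_sd_hz = 0,
              n_harmonics = 1, velocity_harmonic_amps_mm_s = amp,
              amp_mod_sd = 0,
              sensor_noise_rms = list(force_mn = 0, velocity_mm_s = 0),
              seed = seed, ...)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
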