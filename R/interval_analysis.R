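rms <- function(x) sqrt(mean(x^2))

#' Band-limited RMS of one window
#'
#' RMS of the signal content between two frequencies, computed from a
#' Hann-windowed periodogram with Parseval (energy) scaling. The window mean
#' is removed first so DC leakage cannot contaminate the band. For a
#' sinusoid of amplitude A inside the band this returns A/sqrt(2); for white
#' noise it returns the noise RMS times the square root of the band's
#' fraction of `[0, Nyquist]`.
#'
#' @param x Sample vector.
#' @param sample_rate Sampling rate in Hz.
#' @param band `c(low, high)` band edges in Hz; `high` may equal Nyquist.
#' @return Scalar RMS in the input's units.
#' @export
band_rms <- function(x, sample_rate, band) {
  n <- length(x)
  w <- signal::hanning(n)
  X <- stats::fft((x - mean(x)) * w)
  # variance contribution per FFT bin, one-sided
  pw <- Mod(X)^2 / (n^2 * mean(w^2))
  f <- (seq_len(n %/% 2 + 1L) - 1) * sample_rate / n
  half <- pw[seq_along(f)]
  half[2:(n %/% 2)] <- 2 * half[2:(n %/% 2)]
  sel <- f >= band[1] & f <= band[2]
  sqrt(sum(half[sel]))
}

#' Inclusion criteria for one analysis interval
#'
#' Two criteria decide whether a 1024-sample interval enters the tabulated
#' data. Criterion 1 (quiescence): the RMS of the filtered x-axis force must
#' strictly exceed `force_rms_min_mn` (default 10 mN) — an interval at
#' exactly the threshold is excluded. Criterion 2 (optical reflectance): the
#' RMS of the *unfiltered* velocity restricted to the 2.5–5 kHz band must be
#' strictly below `hf_rms_max_mm_s` (default 0.5 mm/s); energy there
#' indicates a poor vibrometer return (high laser incidence angle), not
#' thorax motion.
#'
#' The band RMS is computed spectrally (Hann-windowed periodogram, Parseval
#' scaling): time-domain filtering of an isolated 1024-sample window has
#' edge transients of the same order as the 0.5 mm/s threshold whenever the
#' in-band velocity is tens of mm/s, whereas the spectral definition is
#' transient-free and equals the RMS of the signal content between the band
#' edges.
#'
#' @param window_fx_filtered Filtered x-force samples of one interval (mN).
#' @param window_velocity_unfiltered Raw velocity samples of the same
#'   interval (mm/s).
#' @param sample_rate Sampling rate in Hz.
#' @param force_rms_min_mn,hf_band_hz,hf_rms_max_mm_s Thresholds; defaults
#'   are the study's inclusion criteria.
#' @return Object of class `qc_result`: `pass`, `rms_fx_mn`,
#'   `hf_velocity_rms_mm_s`, `reasons` (subset of `"low_force"`,
#'   `"poor_reflectance"`).
#' @export
qc_interval <- function(window_fx_filtered, window_velocity_unfiltered,
                        sample_rate,
                        force_rms_min_mn = 10,
                        hf_band_hz = c(2500, 5000),
                        hf_rms_max_mm_s = 0.5) {
  if (length(window_fx_filtered) != length(window_velocity_unfiltered)) {
    stop("interval length mismatch between force and velocity windows",
         call. = FALSE)
  }
  rms_fx <- rms(window_fx_filtered)
  rms_hf <- band_rms(window_velocity_unfiltered, sample_rate, hf_band_hz)
  reasons <- character(0)
  if (!(rms_fx > force_rms_min_mn)) reasons <- c(reasons, "low_force")
  if (!(rms_hf < hf_rms_max_mm_s)) reasons <- c(reasons, "poor_reflectance")
  structure(list(pass = length(reasons) == 0L, rms_fx_mn = rms_fx,
                 hf_velocity_rms_mm_s = rms_hf, reasons = reasons),
            class = "qc_result")
}

#' Single-sided amplitude spectrum of a windowed interval
#'
#' Applies a Hamming window (to limit spectral leakage) and an FFT, and
#' scales the result by the window's coherent gain so that a bin-centered
#' sinusoid of amplitude A reports amplitude A. Frequency resolution is
#' `sample_rate / length(x)` — 9.765625 Hz for the default 1024-sample
#' interval at 10 kHz.
#'
#' @param x Sample vector (one interval).
#' @param sample_rate Sampling rate in Hz.
#' @return Data frame with `frequency_hz` and `amplitude` (same unit as the
#'   input), from DC to Nyquist.
#' @export
amplitude_spectrum <- function(x, sample_rate) {
  n <- length(x)
  if (n < 8) stop("interval too short for spectral analysis", call. = FALSE)
  w <- signal::hamming(n)
  cg <- mean(w)                       # coherent gain, sum(w)/n
  X <- stats::fft(x * w)
  half <- n %/% 2 + 1L
  amp <- Mod(X[seq_len(half)]) / (n * cg)
  amp[2:(half - 1L)] <- 2 * amp[2:(half - 1L)]
  data.frame(frequency_hz = (seq_len(half) - 1) * sample_rate / n,
             amplitude = amp)
}

#' Dominant buzz frequency from an amplitude spectrum
#'
#' Finds local spectral maxima whose amplitude strictly exceeds
#' `min_peak_amp` (default 1 mm/s single-sided, i.e. 2 mm/s peak-to-peak),
#' then greedily enforces a minimum spacing of `min_separation_hz`
#' largest-amplitude-first (exact amplitude ties break toward lower
#' frequency). The dominant frequency is the surviving peak with the largest
#' amplitude — where most of the vibrational energy occurs — not necessarily
#' the lowest harmonic.
#'
#' @param spectrum Output of [amplitude_spectrum()].
#' @param min_peak_amp Peak inclusion threshold (input units).
#' @param min_separation_hz Minimum spacing between reported peaks.
#' @return List: `dominant_hz` (`NA` when no peak qualifies) and `peaks`
#'   (data frame of surviving peaks, by decreasing amplitude).
#' @export
dominant_frequency <- function(spectrum, min_peak_amp = 1.0,
                               min_separation_hz = 20) {
  a <- spectrum$amplitude
  f <- spectrum$frequency_hz
  n <- length(a)
  no_peak <- list(dominant_hz = NA_real_,
                  peaks = data.frame(frequency_hz = numeric(0),
                                     amplitude = numeric(0)))
  if (n < 3) return(no_peak)
  i <- 2:(n - 1)
  is_max <- a[i] > a[i - 1] & a[i] >= a[i + 1] & a[i] > min_peak_amp
  cand <- i[is_max]
  if (!length(cand)) return(no_peak)
  cand <- cand[order(-a[cand], f[cand])]
  kept <- integer(0)
  for (j in cand) {
    if (!length(kept) || all(abs(f[j] - f[kept]) >= min_separation_hz)) {
      kept <- c(kept, j)
    }
  }
  list(dominant_hz = f[kept[1]],
       peaks = data.frame(frequency_hz = f[kept], amplitude = a[kept]))
}

#' Run the full per-interval analysis on one recording
#'
#' Applies the analysis bandpass to all four channels, derives displacement
#' and acceleration from the filtered velocity, segments the recording into
#' 50%-overlapping 1024-sample intervals, and for each interval evaluates
#' the inclusion criteria (on filtered Fx and *unfiltered* velocity),
#' estimates the dominant frequency from the Hamming-windowed FFT of the
#' filtered velocity, and tabulates peak (maximum absolute) values of the
#' three forces and the three kinematic quantities.
#'
#' @param rec A [buzz_recording].
#' @param spec [filter_spec()] for the analysis band.
#' @param interval_length,overlap Segmentation parameters.
#' @param force_rms_min_mn,hf_band_hz,hf_rms_max_mm_s QC thresholds, see
#'   [qc_interval()].
#' @param min_peak_amp,min_separation_hz Spectral peak rules, see
#'   [dominant_frequency()].
#' @return Object of class `buzz_analysis`: `metrics` (one row per interval,
#'   columns as in [write_metrics()]), `qc` (per-interval RMS diagnostics)
#'   and `channels` (the filtered channels and derived kinematics, retained
#'   for subinterval regression).
#' @export
analyze_recording <- function(rec, spec = filter_spec(),
                              interval_length = 1024, overlap = 0.5,
                              force_rms_min_mn = 10,
                              hf_band_hz = c(2500, 5000),
                              hf_rms_max_mm_s = 0.5,
                              min_peak_amp = 1.0, min_separation_hz = 20) {
  validate_recording(rec)
  fs <- rec$sample_rate
  filt <- list(
    fx = bandpass(rec$force_x, fs, spec),
    fy = bandpass(rec$force_y, fs, spec),
    fz = bandpass(rec$force_z, fs, spec),
    v = bandpass(rec$velocity, fs, spec)
  )
  kin <- derive_kinematics(filt$v, fs, spec)
  windows <- segment_intervals(length(rec), interval_length, overlap)

  rows <- vector("list", nrow(windows))
  qc_rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    idx <- (windows$start_sample[i] + 1L):(windows$start_sample[i] +
                                             interval_length)
    qc <- qc_interval(filt$fx[idx], rec$velocity[idx], fs,
                      force_rms_min_mn, hf_band_hz, hf_rms_max_mm_s)
    spec_v <- amplitude_spectrum(filt$v[idx], fs)
    dom <- dominant_frequency(spec_v, min_peak_amp, min_separation_hz)
    rows[[i]] <- data.frame(
      bee_id = rec$bee_id,
      interval_index = windows$interval_index[i],
      start_sample = windows$start_sample[i],
      qc_pass = qc$pass,
      qc_reasons = paste(qc$reasons, collapse = ";"),
      dominant_frequency_hz = dom$dominant_hz,
      peak_fx_mn = max(abs(filt$fx[idx])),
      peak_fy_mn = max(abs(filt$fy[idx])),
      peak_fz_mn = max(abs(filt$fz[idx])),
      peak_displacement_um = max(abs(kin$displacement_um[idx])),
      peak_velocity_mm_s = max(abs(filt$v[idx])),
      peak_acceleration_m_s2 = max(abs(kin$acceleration_m_s2[idx]))
    )
    qc_rows[[i]] <- data.frame(
      bee_id = rec$bee_id,
      interval_index = windows$interval_index[i],
      start_sample = windows$start_sample[i],
      qc_pass = qc$pass,
      rms_fx_mn = qc$rms_fx_mn,
      hf_velocity_rms_mm_s = qc$hf_velocity_rms_mm_s,
      qc_reasons = paste(qc$reasons, collapse = ";")
    )
  }
  structure(list(
    metrics = do.call(rbind, rows),
    qc = do.call(rbind, qc_rows),
    channels = c(filt, kin, list(sample_rate = fs, bee_id = rec$bee_id,
                                 post_material = rec$post_material)),
    interval_length = interval_length
  ), class = "buzz_analysis")
}

#' @export
print.buzz_analysis <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<buzz_analysis> %s: %d intervals, %d QC-pass\n",
              x$channels$bee_id, nrow(m), sum(m$qc_pass)))
  ok <- m[m$qc_pass, ]
  if (nrow(ok)) {
    cat(sprintf("  median dominant frequency %.1f Hz, median peak Fx %.1f mN\n",
                stats::median(ok$dominant_frequency_hz, na.rm = TRUE),
                stats::median(ok$peak_fx_mn)))
  }
  invisible(x)
}
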