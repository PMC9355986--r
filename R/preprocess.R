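#' Bandpass filter specification
#'
#' The analysis band is 10–2000 Hz: the high-pass edge removes transducer
#' drift and mounting-table sway, the low-pass edge removes content above the
#' force harmonics of interest. The filter is a Butterworth of the given
#' order per band edge, applied forward-backward (zero phase) so force and
#' velocity peaks stay time-aligned across channels.
#'
#' @param low_cut_hz,high_cut_hz Band edges in Hz.
#' @param order Butterworth design order (poles per band edge).
#' @param zero_phase Apply forward-backward (`filtfilt`)? Single-pass
#'   filtering introduces group delay and is only useful for diagnostics.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut_hz = 10, high_cut_hz = 2000, order = 4,
                        zero_phase = TRUE) {
  if (!(low_cut_hz > 0 && high_cut_hz > low_cut_hz)) {
    stop("need 0 < low_cut_hz < high_cut_hz", call. = FALSE)
  }
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Apply the analysis bandpass to one channel
#'
#' @param x Numeric sample vector.
#' @param sample_rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered vector of the same length.
#' @export
bandpass <- function(x, sample_rate, spec = filter_spec()) {
  nyq <- sample_rate / 2
  if (spec$high_cut_hz >= nyq) {
    stop("parameter error: high_cut_hz must be below Nyquist (",
         nyq, " Hz)", call. = FALSE)
  }
  if (length(x) <= 6L * spec$order) {
    stop("channel too short for filter order", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite input to bandpass", call. = FALSE)
  bf <- signal::butter(spec$order,
                       c(spec$low_cut_hz, spec$high_cut_hz) / nyq,
                       type = "pass")
  if (spec$zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

# Spectral differentiation on the even (mirrored) extension of the signal.
# The extension makes the periodic continuation continuous, so Gibbs ringing
# from the wrap-around discontinuity is confined to a derivative kink at the
# ends instead of polluting the interior.
fft_differentiate <- function(x, sample_rate) {
  n <- length(x)
  xe <- c(x, rev(x))
  N <- 2L * n
  k <- c(0:(N %/% 2), -(N %/% 2 - 1):-1)
  w <- 2i * pi * k * sample_rate / N
  Re(stats::fft(stats::fft(xe) * w, inverse = TRUE))[seq_len(n)] / N
}

cumtrapz <- function(x, sample_rate) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2)) / sample_rate
}

#' Derive thorax displacement and acceleration from velocity
#'
#' Displacement is obtained by cumulative-trapezoid integration followed by
#' the standard zero-phase analysis bandpass, which removes the integration
#' constant and any drift amplified below the 10 Hz edge. Acceleration is
#' obtained by spectral differentiation (even-extension FFT), exact for
#' band-limited content. Both therefore assume the velocity input has no
#' meaningful content below `spec$low_cut_hz`.
#'
#' Units follow the reporting convention: input mm/s yields displacement in
#' µm and acceleration in m/s².
#'
#' @param velocity Velocity samples in mm/s (already bandpassed).
#' @param sample_rate Sampling rate in Hz.
#' @param spec [filter_spec()] used to de-drift the integrated displacement.
#' @return List with numeric vectors `displacement_um` and
#'   `acceleration_m_s2`, each the length of `velocity`.
#' @export
derive_kinematics <- function(velocity, sample_rate, spec = filter_spec()) {
  if (any(!is.finite(velocity))) {
    stop("non-finite velocity input", call. = FALSE)
  }
  if (all(velocity == 0)) {
    z <- numeric(length(velocity))
    return(list(displacement_um = z, acceleration_m_s2 = z))
  }
  disp_mm <- bandpass(cumtrapz(velocity, sample_rate), sample_rate, spec)
  acc <- fft_differentiate(velocity, sample_rate)
  list(displacement_um = disp_mm * 1000, acceleration_m_s2 = acc / 1000)
}

#' Segment a recording into overlapping analysis intervals
#'
#' Intervals are `length` samples long and overlap by `overlap` with the
#' previous interval (default: 1024 samples, 50%), giving a hop of
#' `length * (1 - overlap)` samples. Indexing is 0-based and intervals are
#' half-open `[start, start + length)`; trailing samples that do not fill a
#' complete window are dropped.
#'
#' @param n_samples Recording length in samples.
#' @param length Window length in samples.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @return Data frame with columns `interval_index` (0-based) and
#'   `start_sample` (0-based); zero rows (with a warning) if the recording is
#'   shorter than one window.
#' @export
segment_intervals <- function(n_samples, length = 1024, overlap = 0.5) {
  step <- length * (1 - overlap)
  if (step != round(step) || step < 1) {
    stop("length * (1 - overlap) must be a positive integer", call. = FALSE)
  }
  step <- as.integer(round(step))
  if (n_samples < length) {
    warning("recording shorter than one analysis window; no intervals")
    return(data.frame(interval_index = integer(0), start_sample = integer(0)))
  }
  k <- floor((n_samples - length) / step) + 1
  idx <- seq_len(k) - 1L
  data.frame(interval_index = idx, start_sample = idx * step)
}
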