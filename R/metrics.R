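# Evaluation metrics: spectral SNR, Pearson correlation against a reference
# pulse meter, and the absolute error rate of heart-rate estimates.

#' Spectral signal-to-noise ratio
#'
#' Fourier-transforms the signal and splits the spectrum into a "Signal"
#' band (0.5–15 Hz by default) and a "Noise" band (above 15 Hz up to
#' Nyquist). Returns `20 log10(Signal / Noise)` dB where Signal and Noise
#' are root-sum-square spectral magnitudes over their bands — an amplitude
#' ratio (`mode = "power"` computes `10 log10` of the summed squared
#' magnitudes, an identical number). The DC bin and frequencies below the
#' signal band belong to neither band. The series is demeaned and, by
#' default, Hann-windowed before the transform so that spectral leakage
#' from strong in-band components does not masquerade as noise-band energy;
#' `window = "none"` gives the plain DFT. A signal whose noise band is
#' numerically empty returns `Inf` with attribute `unbounded = TRUE`.
#'
#' @param x a [pulse_signal].
#' @param signal_band length-2 Hz interval (default `c(0.5, 15)`).
#' @param noise_band_start Hz; the noise band is
#'   `(noise_band_start, Nyquist]` (default 15).
#' @param window `"hann"` (default) or `"none"`.
#' @param mode `"amplitude"` (default) or `"power"`.
#' @return SNR in decibels.
#' @export
snr_spectral <- function(x, signal_band = c(0.5, 15), noise_band_start = 15,
                         window = c("hann", "none"),
                         mode = c("amplitude", "power")) {
  window <- match.arg(window)
  mode <- match.arg(mode)
  stopifnot(inherits(x, "pulse_signal"))
  fs <- attr(x, "frame_rate")
  nyq <- fs / 2
  if (nyq <= noise_band_start) {
    stop(sprintf("Nyquist (%g Hz) must exceed noise_band_start (%g Hz): SNR undefined at this frame rate",
                 nyq, noise_band_start), call. = FALSE)
  }
  n <- length(x)
  v <- as.numeric(x) - mean(x)
  if (window == "hann") {
    v <- v * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  }
  mag2 <- Mod(stats::fft(v))^2
  freq <- (seq_len(n) - 1L) * fs / n
  sig <- sum(mag2[freq >= signal_band[1] & freq <= signal_band[2]])
  noi <- sum(mag2[freq > noise_band_start & freq <= nyq])
  if (noi <= 0 || noi < 1e-24 * sig) {
    # noise band indistinguishable from transform roundoff
    return(structure(Inf, unbounded = TRUE))
  }
  if (mode == "amplitude") 20 * log10(sqrt(sig) / sqrt(noi)) else
    10 * log10(sig / noi)
}

#' Pearson correlation between two pulse signals
#'
#' Standard signed product-moment coefficient; both series must be equal
#' length and non-constant. An optional lag search maximizes |rho| over
#' integer-frame lags up to `max_lag_s` (off by default: zero lag assumed).
#'
#' @param a,b [pulse_signal]s of equal length >= 2.
#' @param max_lag_s if > 0, search lags in `[-max_lag_s, max_lag_s]` seconds
#'   and return the correlation of largest magnitude (default 0).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b, max_lag_s = 0) {
  stopifnot(inherits(a, "pulse_signal"), inherits(b, "pulse_signal"))
  va <- as.numeric(a); vb <- as.numeric(b)
  if (length(va) != length(vb) || length(va) < 2L) {
    stop("signals must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("correlation undefined for a constant signal", call. = FALSE)
  }
  if (max_lag_s <= 0) return(stats::cor(va, vb))
  fs <- attr(a, "frame_rate")
  max_lag <- floor(max_lag_s * fs)
  best <- 0
  n <- length(va)
  for (lag in seq(-max_lag, max_lag)) {
    ia <- max(1L, 1L + lag):min(n, n + lag)
    ib <- ia - lag
    if (length(ia) < 2L) next
    r <- stats::cor(va[ia], vb[ib])
    if (is.finite(r) && abs(r) > abs(best)) best <- r
  }
  best
}

#' Absolute error rate of a heart-rate estimate
#'
#' `AER = |HR_gt - HR_est| / HR_gt * 100`, in percent.
#'
#' @param hr_gt ground-truth heart rate in bpm, > 0.
#' @param hr_ev estimated heart rate in bpm.
#' @return AER in percent (>= 0).
#' @export
absolute_error_rate <- function(hr_gt, hr_ev) {
  stopifnot_scalar_number(hr_gt, "hr_gt", min = 0, strict = TRUE)
  stopifnot_scalar_number(hr_ev, "hr_ev")
  abs(hr_gt - hr_ev) / hr_gt * 100
}

#' Resample a reference pulse-meter signal onto the camera frame grid
#'
#' The pulse meter and camera run on different clocks; this linearly
#' interpolates the reference onto the camera's frame times over a common
#' duration, assuming the two started simultaneously (zero lag).
#'
#' @param ref_values numeric reference samples.
#' @param ref_rate reference sampling rate in Hz, > 0.
#' @param target_rate camera frame rate in Hz, > 0.
#' @param duration_s common duration in seconds; the reference must cover it.
#' @return A [pulse_signal] at `target_rate` with
#'   `floor(duration_s * target_rate)` samples.
#' @export
align_reference <- function(ref_values, ref_rate, target_rate, duration_s) {
  stopifnot_scalar_number(ref_rate, "ref_rate", min = 0, strict = TRUE)
  stopifnot_scalar_number(target_rate, "target_rate", min = 0, strict = TRUE)
  stopifnot_scalar_number(duration_s, "duration_s", min = 0, strict = TRUE)
  ref_values <- as.numeric(ref_values)
  t_ref <- (seq_along(ref_values) - 1L) / ref_rate
  n_out <- floor(duration_s * target_rate)
  t_out <- (seq_len(n_out) - 1L) / target_rate
  if (max(t_ref) < max(t_out)) {
    stop(sprintf("reference (%.3g s) shorter than requested duration (%.3g s)",
                 max(t_ref), max(t_out)), call. = FALSE)
  }
  if (length(unique(ref_values)) == 1L) {
    return(pulse_signal(rep(ref_values[1L], n_out), target_rate))
  }
  y <- stats::approx(t_ref, ref_values, xout = t_out, method = "linear")$y
  pulse_signal(y, target_rate)
}

#' Assemble a metrics report for one method at one stage
#'
#' @param correlation Pearson correlation against the reference (or `NA`).
#' @param snr_db spectral SNR in dB.
#' @param hr_estimated,hr_reference heart rates in bpm (or `NA` for stages
#'   where HR is not computed).
#' @param method,stage labels.
#' @return An object of class `metrics_report` (also a one-row data.frame
#'   via [as.data.frame.metrics_report]).
#' @export
metrics_report <- function(method, stage, correlation = NA_real_,
                           snr_db = NA_real_, hr_estimated = NA_real_,
                           hr_reference = NA_real_) {
  aer <- if (is.finite(hr_estimated) && is.finite(hr_reference)) {
    absolute_error_rate(hr_reference, hr_estimated)
  } else NA_real_
  structure(list(method = method, stage = stage,
                 correlation = as.numeric(correlation),
                 snr_db = as.numeric(snr_db),
                 hr_estimated = as.numeric(hr_estimated),
                 hr_reference = as.numeric(hr_reference),
                 aer_percent = aer),
            class = "metrics_report")
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(method = x$method, stage = x$stage, correlation = x$correlation,
             snr_db = x$snr_db, hr_estimated = x$hr_estimated,
             hr_reference = x$hr_reference, aer_percent = x$aer_percent,
             stringsAsFactors = FALSE)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s / %s: corr = %s, SNR = %s dB, HR = %s bpm, AER = %s%%\n",
              x$method, x$stage,
              formatC(x$correlation, digits = 3),
              formatC(x$snr_db, digits = 3),
              formatC(x$hr_estimated, digits = 4),
              formatC(x$aer_percent, digits = 3)))
  invisible(x)
}
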