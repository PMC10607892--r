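# Sensor-noise estimation from an artificial-skin-patch ROI.
#
# The patch has constant reflectance, so any temporal fluctuation of its
# ROI-mean series is sensor noise. The per-band standard deviation of that
# series estimates the noise magnitude; the larger of the two bands is
# carried forward. Gaussian noise at that magnitude defines Rnn = <n n'>.

#' Estimate noise magnitude from a patch series
#'
#' Computes, per band, the sample standard deviation (n - 1 denominator) of
#' the patch ROI-mean time series, and selects the larger of the two bands.
#' By default the series is density-transformed first so the estimate shares
#' units with the observations the noise model is applied to; set
#' `on = "counts"` to measure raw pixel-count fluctuation instead.
#'
#' @param patch_bands a [band_series] of patch ROI means (two bands,
#'   >= 2 frames).
#' @param on `"density"` (default) or `"counts"`.
#' @param floor_count clipping floor passed to [to_density].
#' @return An object of class `noise_estimate` with fields `sigma_per_band`,
#'   `sigma_selected`, `units`, `n_frames`.
#' @export
patch_noise_sigma <- function(patch_bands, on = c("density", "counts"),
                              floor_count = 1) {
  on <- match.arg(on)
  if (!inherits(patch_bands, "band_series")) {
    stop("`patch_bands` must be a band_series", call. = FALSE)
  }
  if (nrow(patch_bands) < 2L) {
    stop("patch series needs at least 2 frames to estimate a standard deviation",
         call. = FALSE)
  }
  x <- if (on == "density") {
    unclass(to_density(patch_bands, floor_count = floor_count))
  } else {
    unclass(patch_bands)
  }
  sig <- apply(x, 2L, stats::sd)
  names(sig) <- attr(patch_bands, "band_ids")
  structure(list(sigma_per_band = sig,
                 sigma_selected = max(sig),
                 units = if (on == "density") "density" else "counts",
                 n_frames = nrow(patch_bands)),
            class = "noise_estimate")
}

#' Noise autocorrelation matrix Rnn
#'
#' For i.i.d. zero-mean Gaussian noise of standard deviation `sigma` per
#' band, `Rnn = <n n'> = sigma^2 I`. The analytic mode returns this exact
#' second moment; the sampled mode draws `n_samples` noise 2-vectors and
#' returns the empirical mean of `n n'`, mirroring how a measured sigma is
#' turned into generated noise in practice.
#'
#' @param sigma noise standard deviation, >= 0.
#' @param mode `"analytic"` (default) or `"sampled"`.
#' @param n_samples draws for the sampled mode (default 1e6, >= 2).
#' @param seed optional integer seed for the sampled mode.
#' @return An `autocorrelation_matrix` with role `"noise"`.
#' @export
build_noise_autocorrelation <- function(sigma, mode = c("analytic", "sampled"),
                                        n_samples = 1e6, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(sigma, "sigma", min = 0)
  if (mode == "analytic") {
    return(autocorrelation_matrix(diag(sigma^2, 2), role = "noise",
                                  provenance = "analytic"))
  }
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("sampled mode requires `n_samples` >= 2", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  n <- with_seed(seed, matrix(stats::rnorm(2L * n_samples, 0, sigma),
                              ncol = 2L))
  autocorrelation_matrix(crossprod(n) / n_samples, role = "noise",
                         provenance = "sampled", n_samples = n_samples,
                         seed = seed)
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma per band (%s units): %s; selected (max) %.6g over %d frames\n",
              x$units,
              paste(sprintf("%s = %.6g", names(x$sigma_per_band),
                            x$sigma_per_band), collapse = ", "),
              x$sigma_selected, x$n_frames))
  invisible(x)
}
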