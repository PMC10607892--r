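# Forward observation model: pigment components -> band densities.
#
# In the near-infrared, skin reflectance in a band reduces to two absorbing
# contributions: hemoglobin in the dermis (pulsatile) and a shade term from
# illumination geometry (common to both bands, temporally fixed). In density
# space (negative log of normalized pixel values) these combine linearly,
#   v = F r + n,
# with v the 2-vector of band densities, r = (hemoglobin, shade), F the 2x2
# system matrix lumping spectral transmittance, radiance and sensitivity,
# and n additive sensor noise.

#' Two-band pixel-value time series
#'
#' Container for the per-frame mean pixel value of two camera bands over a
#' fixed-rate recording (e.g. the face-ROI means of a two-band near-infrared
#' video).
#'
#' @param values numeric matrix with one row per frame and one column per
#'   band (exactly two bands), in camera counts.
#' @param frame_rate frames per second, > 0.
#' @param band_ids labels for the two bands (default `c("800", "930")`,
#'   center wavelengths in nm).
#' @param max_value sensor full-scale count (default 65535 for a 16-bit
#'   sensor). All values must lie in `[0, max_value]`.
#' @return An object of class `band_series`: the values matrix with
#'   attributes `frame_rate`, `band_ids` and `max_value`.
#' @export
band_series <- function(values, frame_rate, band_ids = c("800", "930"),
                        max_value = 65535) {
  values <- as.matrix(values)
  if (ncol(values) != 2L) {
    stop("`values` must have exactly two bands (columns), got ", ncol(values),
         call. = FALSE)
  }
  stopifnot_scalar_number(frame_rate, "frame_rate", min = 0, strict = TRUE)
  stopifnot_scalar_number(max_value, "max_value", min = 0, strict = TRUE)
  if (length(band_ids) != 2L) stop("`band_ids` must have length 2", call. = FALSE)
  if (any(!is.finite(values))) stop("band values must be finite", call. = FALSE)
  if (any(values < 0) || any(values > max_value)) {
    stop("band values must lie in [0, max_value]", call. = FALSE)
  }
  colnames(values) <- as.character(band_ids)
  structure(values,
            frame_rate = frame_rate,
            band_ids = as.character(band_ids),
            max_value = max_value,
            class = c("band_series", "matrix"))
}

#' Two-component density time series
#'
#' Per-frame 2-vectors of band densities `v` (negative log of normalized
#' pixel values), the observation on which component separation operates.
#'
#' @param vectors numeric matrix, one row per frame, exactly two columns.
#' @param frame_rate frames per second, > 0.
#' @return An object of class `density_series`.
#' @export
density_series <- function(vectors, frame_rate) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 2L) {
    stop("density vectors must have exactly 2 components", call. = FALSE)
  }
  if (any(!is.finite(vectors))) stop("density values must be finite", call. = FALSE)
  stopifnot_scalar_number(frame_rate, "frame_rate", min = 0, strict = TRUE)
  structure(vectors, frame_rate = frame_rate,
            class = c("density_series", "matrix"))
}

#' Two-component pigment time series
#'
#' Per-frame estimates (or ground truth) of `r = (hemoglobin, shade)`.
#' The hemoglobin column is the raw pulse-wave signal.
#'
#' @param vectors numeric matrix, one row per frame, two columns
#'   (hemoglobin, shade).
#' @param frame_rate frames per second, > 0.
#' @param method_tag which estimator produced the series: `"conventional"`,
#'   `"wiener"` or `"ground_truth"`.
#' @return An object of class `pigment_series`.
#' @export
pigment_series <- function(vectors, frame_rate,
                           method_tag = c("conventional", "wiener",
                                          "ground_truth")) {
  method_tag <- match.arg(method_tag)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 2L) {
    stop("pigment vectors must have exactly 2 components", call. = FALSE)
  }
  if (any(!is.finite(vectors))) stop("pigment values must be finite", call. = FALSE)
  stopifnot_scalar_number(frame_rate, "frame_rate", min = 0, strict = TRUE)
  colnames(vectors) <- c("hemoglobin", "shade")
  structure(vectors, frame_rate = frame_rate, method_tag = method_tag,
            class = c("pigment_series", "matrix"))
}

#' Extract the hemoglobin track of a pigment series as a pulse signal
#'
#' @param r a `pigment_series`.
#' @return A [pulse_signal] (stage `"raw"`) holding the hemoglobin column.
#' @export
hemoglobin_signal <- function(r) {
  stopifnot(inherits(r, "pigment_series"))
  pulse_signal(as.numeric(r[, 1L]), attr(r, "frame_rate"), stage = "raw")
}

#' Build the 2x2 system matrix F
#'
#' `F` maps pigment components to band densities. Its first column is the
#' relative hemoglobin absorbance at the two selected bands; its second
#' column is the shade direction, `(1, 1)` by default since shade scales
#' both bands equally. The matrix is configuration, not estimation: the
#' defaults are a documented placeholder with the structural properties of
#' a two-band near-infrared system (near-collinear columns).
#'
#' @param hb_column length-2 relative hemoglobin absorbances, default
#'   `c(1.0, 0.9)` for bands at 800 and 930 nm.
#' @param shade_column length-2 shade direction, default `c(1, 1)`.
#' @param band_ids labels of the two bands.
#' @param tol singularity threshold on the condition number (default 1e12).
#' @return An object of class `system_matrix` (a 2x2 matrix with columns
#'   `hemoglobin`, `shade`).
#' @export
build_forward_matrix <- function(hb_column = c(1.0, 0.9),
                                 shade_column = c(1, 1),
                                 band_ids = c("800", "930"),
                                 tol = 1e12) {
  if (length(hb_column) != 2L || length(shade_column) != 2L) {
    stop("`hb_column` and `shade_column` must each have length 2", call. = FALSE)
  }
  if (any(!is.finite(c(hb_column, shade_column)))) {
    stop("matrix columns must be finite", call. = FALSE)
  }
  f <- cbind(hemoglobin = as.numeric(hb_column),
             shade = as.numeric(shade_column))
  rownames(f) <- as.character(band_ids)
  check_nonsingular(f, "system matrix F", tol = tol)
  structure(f, band_ids = as.character(band_ids),
            class = c("system_matrix", "matrix"))
}

#' Convert pixel values to densities
#'
#' Applies the density transform `-log(clip(pixel, floor_count, max_value) /
#' max_value)` per frame and band. Counts are normalized by the sensor full
#' scale so densities are dimensionless and non-negative; the clipping floor
#' avoids `log(0)` for dead pixels.
#'
#' @param bands a [band_series] with exactly two bands.
#' @param floor_count clipping floor for zero counts, >= 1 (default 1).
#' @return A [density_series] at the same frame rate.
#' @export
to_density <- function(bands, floor_count = 1) {
  if (!inherits(bands, "band_series")) {
    stop("`bands` must be a band_series", call. = FALSE)
  }
  stopifnot_scalar_number(floor_count, "floor_count", min = 1)
  max_value <- attr(bands, "max_value")
  if (max_value <= 0) stop("`max_value` must be positive", call. = FALSE)
  clipped <- pmin(pmax(unclass(bands), floor_count), max_value)
  density_series(-log(clipped / max_value), attr(bands, "frame_rate"))
}

#' Convert densities back to pixel counts
#'
#' Inverse of [to_density]: `pixel = max_value * exp(-density)`. Used by the
#' synthetic generator; exact round-trip for counts in
#' `[floor_count, max_value]` (before integer quantization).
#'
#' @param v a [density_series].
#' @param max_value sensor full-scale count.
#' @param band_ids band labels for the resulting series.
#' @param quantize round to integer counts (default FALSE).
#' @return A [band_series].
#' @export
from_density <- function(v, max_value = 65535, band_ids = c("800", "930"),
                         quantize = FALSE) {
  stopifnot(inherits(v, "density_series"))
  counts <- max_value * exp(-unclass(v))
  if (quantize) counts <- round(counts)
  band_series(pmin(pmax(counts, 0), max_value), attr(v, "frame_rate"),
              band_ids = band_ids, max_value = max_value)
}

#' Simulate observations from the forward model
#'
#' Applies `v = F r + n` per frame, with `n` i.i.d. zero-mean Gaussian of
#' standard deviation `noise_sigma` per component. `noise_sigma = 0` gives
#' the noise-free model exactly.
#'
#' @param f a `system_matrix`.
#' @param r a [pigment_series].
#' @param noise_sigma noise standard deviation in density units, >= 0.
#' @param seed optional integer seed for the noise draw (the caller's RNG
#'   state is untouched).
#' @return A [density_series].
#' @export
forward_observe <- function(f, r, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(f, "system_matrix"), inherits(r, "pigment_series"))
  stopifnot_scalar_number(noise_sigma, "noise_sigma", min = 0)
  v <- unclass(r) %*% t(unclass(f))
  if (noise_sigma > 0) {
    n <- with_seed(seed, matrix(stats::rnorm(length(v), 0, noise_sigma),
                                nrow = nrow(v)))
    v <- v + n
  }
  density_series(v, attr(r, "frame_rate"))
}

#' @export
print.band_series <- function(x, ...) {
  cat(sprintf("<band_series> %d frames x 2 bands (%s) @ %.6g fps, full scale %g\n",
              nrow(x), paste(attr(x, "band_ids"), collapse = ", "),
              attr(x, "frame_rate"), attr(x, "max_value")))
  invisible(x)
}

#' @export
print.pigment_series <- function(x, ...) {
  cat(sprintf("<pigment_series> %d frames @ %.6g fps, method = %s\n",
              nrow(x), attr(x, "frame_rate"), attr(x, "method_tag")))
  invisible(x)
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf("<density_series> %d frames @ %.6g fps\n",
              nrow(x), attr(x, "frame_rate")))
  invisible(x)
}

#' @export
print.system_matrix <- function(x, ...) {
  cat("<system_matrix> bands x (hemoglobin, shade):\n")
  print(matrix(as.numeric(x), 2, 2,
               dimnames = list(attr(x, "band_ids"),
                               c("hemoglobin", "shade"))))
  invisible(x)
}
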