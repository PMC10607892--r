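# Synthetic two-band session generator.
#
# Emulates the statistical structure the separation method assumes: a
# periodic hemoglobin pulsation over a fixed baseline, a temporally constant
# shade component, the linear density-space observation v = F r + n with
# i.i.d. Gaussian sensor noise, a constant-reflectance patch series carrying
# noise of matched magnitude, and a clean higher-rate pulse-meter reference.
# Every draw is reproducible from the config seed.

#' Configuration of a synthetic session
#'
#' Defaults reproduce the recording geometry of a 30 s, 66.5 fps two-band
#' near-infrared capture (1995 frames) with a near-collinear system matrix,
#' and a sensor-noise level at which the conventional inverse buries the
#' pulse while the Wiener estimate retains it.
#'
#' @param duration_s recording length in seconds (default 30).
#' @param frame_rate frames per second (default 66.5).
#' @param f0 pulse fundamental in Hz (default 1.2, i.e. 72 bpm); values in
#'   the cardiac band 0.75–4 Hz are recommended.
#' @param harmonic_amps relative amplitudes of harmonics 1..K (default
#'   `c(1, 0.35)`).
#' @param hb_baseline hemoglobin baseline density (default 0.30).
#' @param hb_pulse_amp hemoglobin pulsation amplitude in density units
#'   (default 0.005).
#' @param shade_value fixed shade density (default 0.40).
#' @param drift optional low-frequency hemoglobin trend,
#'   `list(amplitude =, frequency =)` in density units / Hz (default none).
#' @param noise_sigma sensor-noise standard deviation in density units
#'   (default 0.0025).
#' @param f system matrix (default [build_forward_matrix] defaults).
#' @param max_value sensor full scale (default 65535).
#' @param patch_density density of the constant patch (default 0.5).
#' @param reference_rate pulse-meter sampling rate in Hz (default 256).
#' @param reference_invert flip the reference sign convention (default
#'   FALSE: reference increases with hemoglobin absorption).
#' @param seed integer seed (default 1).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_s = 30, frame_rate = 66.5, f0 = 1.2,
                             harmonic_amps = c(1, 0.35), hb_baseline = 0.30,
                             hb_pulse_amp = 0.005, shade_value = 0.40,
                             drift = NULL, noise_sigma = 0.0025,
                             f = build_forward_matrix(), max_value = 65535,
                             patch_density = 0.5, reference_rate = 256,
                             reference_invert = FALSE, seed = 1) {
  stopifnot_scalar_number(duration_s, "duration_s", min = 0, strict = TRUE)
  stopifnot_scalar_number(frame_rate, "frame_rate", min = 0, strict = TRUE)
  stopifnot_scalar_number(f0, "f0", min = 0, strict = TRUE)
  stopifnot_scalar_number(noise_sigma, "noise_sigma", min = 0)
  stopifnot_scalar_number(hb_pulse_amp, "hb_pulse_amp", min = 0)
  stopifnot(inherits(f, "system_matrix"))
  if (!is.null(drift)) {
    stopifnot(is.list(drift), !is.null(drift$amplitude), !is.null(drift$frequency))
  }
  structure(list(duration_s = duration_s, frame_rate = frame_rate, f0 = f0,
                 harmonic_amps = harmonic_amps, hb_baseline = hb_baseline,
                 hb_pulse_amp = hb_pulse_amp, shade_value = shade_value,
                 drift = drift, noise_sigma = noise_sigma, f = f,
                 max_value = max_value, patch_density = patch_density,
                 reference_rate = reference_rate,
                 reference_invert = reference_invert, seed = seed),
            class = "synthetic_config")
}

#' Periodic pulse waveform
#'
#' Harmonic-sum stand-in for a photoplethysmographic waveform:
#' `sum_k amps[k] sin(2 pi k f0 t)`, normalized to unit peak amplitude.
#'
#' @param t numeric time grid in seconds.
#' @param f0 fundamental frequency in Hz, > 0.
#' @param harmonic_amps amplitudes of harmonics 1..K; at least one nonzero.
#' @return Numeric series on `t` with peak absolute value 1 and period
#'   `1 / f0`.
#' @export
pulse_waveform <- function(t, f0, harmonic_amps = c(1, 0.35)) {
  stopifnot_scalar_number(f0, "f0", min = 0, strict = TRUE)
  if (!length(harmonic_amps) || all(harmonic_amps == 0)) {
    stop("at least one harmonic amplitude must be nonzero", call. = FALSE)
  }
  w <- rep(0, length(t))
  for (k in seq_along(harmonic_amps)) {
    w <- w + harmonic_amps[k] * sin(2 * pi * k * f0 * t)
  }
  # normalize to unit peak over a densely sampled period
  tp <- seq(0, 1 / f0, length.out = 4096L)
  wp <- rep(0, length(tp))
  for (k in seq_along(harmonic_amps)) {
    wp <- wp + harmonic_amps[k] * sin(2 * pi * k * f0 * tp)
  }
  w / max(abs(wp))
}

#' Generate a synthetic two-band session
#'
#' Builds the ground-truth pigment series `r(t) = (hb_baseline +
#' hb_pulse_amp * waveform + drift, shade_value)`, observes it through the
#' forward model with Gaussian sensor noise, converts to quantized pixel
#' counts, and adds a constant-reflectance patch series carrying count noise
#' of matched density-space magnitude, plus a clean pulse-meter reference at
#' its own rate.
#'
#' @param cfg a [synthetic_config].
#' @return An object of class `synthetic_session` with fields `bands`
#'   (face [band_series]), `patch_bands`, `truth_pigments`
#'   ([pigment_series], `method_tag = "ground_truth"`), `reference_signal`
#'   (numeric), `reference_rate`, `truth_hr` (`60 * f0` bpm) and `config`.
#' @export
synthesize_session <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- floor(cfg$duration_s * cfg$frame_rate)
  t <- (seq_len(n) - 1L) / cfg$frame_rate
  w <- pulse_waveform(t, cfg$f0, cfg$harmonic_amps)
  hb <- cfg$hb_baseline + cfg$hb_pulse_amp * w
  if (!is.null(cfg$drift)) {
    hb <- hb + cfg$drift$amplitude * sin(2 * pi * cfg$drift$frequency * t)
  }
  truth <- pigment_series(cbind(hb, rep(cfg$shade_value, n)), cfg$frame_rate,
                          method_tag = "ground_truth")
  with_seed(cfg$seed, {
    v <- unclass(truth) %*% t(matrix(as.numeric(cfg$f), 2, 2))
    if (cfg$noise_sigma > 0) {
      v <- v + matrix(stats::rnorm(2L * n, 0, cfg$noise_sigma), ncol = 2L)
    }
    counts <- round(cfg$max_value * exp(-v))
    counts <- pmin(pmax(counts, 0), cfg$max_value)
    bands <- band_series(counts, cfg$frame_rate,
                         band_ids = attr(cfg$f, "band_ids"),
                         max_value = cfg$max_value)
    # patch: constant reflectance; count noise scaled so its density-space
    # magnitude matches the face-noise sigma (d(density) = -d(count)/count)
    patch_count <- cfg$max_value * exp(-cfg$patch_density)
    patch <- matrix(patch_count, n, 2L)
    if (cfg$noise_sigma > 0) {
      patch <- patch + matrix(stats::rnorm(2L * n, 0,
                                           patch_count * cfg$noise_sigma),
                              ncol = 2L)
    }
    patch <- round(pmin(pmax(patch, 1), cfg$max_value))
    patch_bands <- band_series(patch, cfg$frame_rate,
                               band_ids = attr(cfg$f, "band_ids"),
                               max_value = cfg$max_value)
    n_ref <- floor(cfg$duration_s * cfg$reference_rate)
    t_ref <- (seq_len(n_ref) - 1L) / cfg$reference_rate
    ref <- pulse_waveform(t_ref, cfg$f0, cfg$harmonic_amps)
    if (cfg$reference_invert) ref <- -ref
    structure(list(bands = bands, patch_bands = patch_bands,
                   truth_pigments = truth, reference_signal = ref,
                   reference_rate = cfg$reference_rate,
                   truth_hr = 60 * cfg$f0, config = cfg),
              class = "synthetic_session")
  })
}

#' Default ROI layout for synthetic frame stacks
#'
#' @param image_size square frame side in pixels.
#' @return Named list of [roi_spec]s: a `face` ROI in the upper-left
#'   quadrant and a `patch` ROI in the lower-right.
#' @export
default_roi_layout <- function(image_size = 64) {
  half <- floor(image_size / 2)
  list(face = roi_spec("face", 0, 0, half, half),
       patch = roi_spec("patch", image_size - half, image_size - half,
                        half, half))
}

#' Write a synthetic session as a two-band frame stack on disk
#'
#' Renders per-frame 16-bit TIFF images (one file per frame and band) where
#' the face ROI carries the session's pixel series plus i.i.d. spatial
#' noise, the patch ROI carries the patch series, and the background is
#' mid-scale. A JSON manifest records band ids, frame rate, full scale, ROI
#' layout and seed; the reference signal is written as CSV
#' (`time_s, value`). Reading the stack back through [read_frame_stack] and
#' [extract_roi_mean] reproduces the session's band series up to
#' spatial-averaging noise (exactly, up to quantization, when
#' `spatial_noise_sd = 0`).
#'
#' @param cfg a [synthetic_config].
#' @param dir output directory (created if needed).
#' @param image_size square frame side in pixels (default 64); must contain
#'   the ROI layout.
#' @param roi_layout named list with `face` and `patch` [roi_spec]s
#'   (default [default_roi_layout]).
#' @param spatial_noise_sd standard deviation of i.i.d. spatial count noise
#'   added per pixel inside the face ROI (default 0).
#' @return The manifest path, invisibly.
#' @export
synthesize_frames <- function(cfg, dir, image_size = 64,
                              roi_layout = default_roi_layout(image_size),
                              spatial_noise_sd = 0) {
  stopifnot(inherits(cfg, "synthetic_config"))
  session <- synthesize_session(cfg)
  for (roi in roi_layout) {
    if (roi$x0 + roi$width > image_size || roi$y0 + roi$height > image_size) {
      stop(sprintf("ROI '%s' exceeds the %dx%d frame", roi$name,
                   image_size, image_size), call. = FALSE)
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  band_ids <- attr(session$bands, "band_ids")
  n <- nrow(session$bands)
  max_value <- cfg$max_value
  files <- vector("list", 2L)
  with_seed(cfg$seed + 1L, {
    for (b in 1:2) {
      files[[b]] <- character(n)
      for (i in seq_len(n)) {
        img <- matrix(max_value / 2, image_size, image_size)
        face <- roi_layout$face
        fv <- matrix(session$bands[i, b], face$height, face$width)
        if (spatial_noise_sd > 0) {
          fv <- fv + matrix(stats::rnorm(face$height * face$width, 0,
                                         spatial_noise_sd),
                            face$height, face$width)
        }
        img[face$y0 + seq_len(face$height), face$x0 + seq_len(face$width)] <- fv
        patch <- roi_layout$patch
        img[patch$y0 + seq_len(patch$height),
            patch$x0 + seq_len(patch$width)] <- session$patch_bands[i, b]
        img <- round(pmin(pmax(img, 0), max_value))
        fn <- sprintf("frame_%05d_band%s.tif", i, band_ids[b])
        tiff::writeTIFF(img / max_value, file.path(dir, fn),
                        bits.per.sample = 16L)
        files[[b]][i] <- fn
      }
    }
  })
  names(files) <- band_ids
  ref_path <- file.path(dir, "reference.csv")
  t_ref <- (seq_along(session$reference_signal) - 1L) / session$reference_rate
  utils::write.csv(data.frame(time_s = t_ref,
                              value = session$reference_signal),
                   ref_path, row.names = FALSE, quote = FALSE)
  manifest <- list(band_ids = band_ids, frame_rate = cfg$frame_rate,
                   max_value = max_value, n_frames = n,
                   image_size = image_size,
                   rois = lapply(roi_layout, unclass),
                   frames = files, reference = "reference.csv",
                   seed = cfg$seed)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d frames @ %.6g fps, f0 = %.3g Hz (HR %.4g bpm), noise sigma %.3g\n",
              nrow(x$bands), x$config$frame_rate, x$config$f0, x$truth_hr,
              x$config$noise_sigma))
  invisible(x)
}
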