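fs <- 66.5
tt <- function(dur) (seq_len(floor(dur * fs)) - 1) / fs

test_that("smoothness-priors detrending removes constants and ramps, keeps cardiac tones", {
  n <- 1995
  const <- pulse_signal(rep(5, n), fs)
  out <- detrend_smoothness_priors(const, 300)
  expect_lt(max(abs(out)), 1e-8 * 5)
  expect_identical(attr(out, "stage"), "detrended")

  ramp <- pulse_signal(seq(0, 10, length.out = n), fs)
  out <- detrend_smoothness_priors(ramp, 300)
  expect_lt(max(abs(out)), 0.01 * 10)

  tone <- pulse_signal(sin(2 * pi * 1.2 * tt(30)), fs)
  out <- detrend_smoothness_priors(tone, 300)
  expect_gt(cor(as.numeric(out), as.numeric(tone)), 0.99)

  expect_error(detrend_smoothness_priors(pulse_signal(c(1, 2), fs)),
               "at least 3")
  expect_error(detrend_smoothness_priors(const, lambda_reg = 0), "lambda_reg")
})

test_that("bandpass passes the cardiac band and rejects the trend band", {
  zero <- bandpass(pulse_signal(rep(0, 2000), fs))
  expect_true(all(zero == 0))
  expect_identical(attr(zero, "stage"), "bandpassed")

  t <- tt(60)
  inband <- bandpass(pulse_signal(sin(2 * pi * 1.5 * t), fs))
  mid <- seq(1000, length(t) - 1000)  # avoid edge transients
  amp <- max(abs(inband[mid]))
  expect_equal(amp, 1, tolerance = 0.05)

  slow <- bandpass(pulse_signal(sin(2 * pi * 0.1 * t), fs))
  amp_slow <- max(abs(slow[mid]))
  expect_lt(20 * log10(amp_slow / 1), -20)

  expect_error(bandpass(pulse_signal(rep(0, 100), fs), f_lo = 0.75,
                        f_hi = 40), "Nyquist")
  expect_error(bandpass(pulse_signal(rep(0, 100), fs), f_lo = 5, f_hi = 4),
               "f_lo < f_hi")
})

test_that("bandpass is linear", {
  set.seed(3)
  x <- rnorm(1500)
  y <- rnorm(1500)
  bx <- as.numeric(bandpass(pulse_signal(x, fs)))
  by <- as.numeric(bandpass(pulse_signal(y, fs)))
  bxy <- as.numeric(bandpass(pulse_signal(2 * x - 3 * y, fs)))
  expect_equal(bxy, 2 * bx - 3 * by, tolerance = 1e-8)
})

test_that("detrend + bandpass output is mean-free", {
  set.seed(4)
  x <- pulse_signal(0.3 + 0.005 * sin(2 * pi * 1.2 * tt(30)) +
                      rnorm(1995, 0, 0.002), fs)
  y <- bandpass(detrend_smoothness_priors(x))
  expect_lt(abs(mean(y)), 1e-6 * sqrt(mean(as.numeric(y)^2)))
})

test_that("peak detection finds one peak per period of a clean pulse", {
  x <- pulse_signal(sin(2 * pi * 1.0 * tt(30)), fs, stage = "bandpassed")
  p <- detect_peaks(x)
  expect_true(length(p$indices) %in% c(29, 30))
  expect_true(all(abs(p$rr_intervals - 1.0) <= 1 / fs + 1e-9))
  expect_equal(p$mean_rr, mean(p$rr_intervals))
  expect_true(all(diff(p$indices) > 0))

  const <- pulse_signal(rep(1, 500), fs, stage = "bandpassed")
  expect_length(detect_peaks(const)$indices, 0)
})

test_that("close competing maxima resolve to the higher peak", {
  # two local maxima 0.1 s apart (heights 1 and 2) within min_rr_s = 0.25
  n <- round(fs)
  x <- rep(0, n)
  i1 <- 30
  i2 <- i1 + round(0.1 * fs)
  x[i1 + c(-1, 0, 1)] <- c(0.5, 1, 0.5)
  x[i2 + c(-1, 0, 1)] <- c(1, 2, 1)
  p <- detect_peaks(pulse_signal(x, fs, stage = "bandpassed"),
                    min_rr_s = 0.25, height_quantile = NULL,
                    prominence_frac = NULL)
  expect_identical(p$indices, as.integer(i2))
})

test_that("peak detection is invariant to positive affine rescaling", {
  set.seed(6)
  x <- as.numeric(bandpass(pulse_signal(
    sin(2 * pi * 1.3 * tt(30)) + 0.2 * rnorm(1995), fs)))
  p1 <- detect_peaks(pulse_signal(x, fs, stage = "bandpassed"))
  p2 <- detect_peaks(pulse_signal(3.7 * x + 11, fs, stage = "bandpassed"))
  expect_identical(p1$indices, p2$indices)
})

test_that("peak detection warns on a non-bandpassed stage", {
  x <- pulse_signal(sin(2 * pi * tt(10)), fs)
  expect_warning(detect_peaks(x), "bandpassed")
})

test_that("heart rate is 60 over the mean RR interval", {
  mk_peaks <- function(rr) {
    idx <- cumsum(c(1, round(rr * fs)))
    structure(list(indices = idx, rr_intervals = diff(idx) / fs,
                   mean_rr = mean(diff(idx) / fs), frame_rate = fs),
              class = "peak_set")
  }
  expect_equal(heart_rate(mk_peaks(rep(1.0, 10))), 60, tolerance = 0.01)
  expect_equal(heart_rate(mk_peaks(rep(0.5, 10))), 120, tolerance = 0.02)
  # RR (1.0, 0.8, 1.2) s -> mean 1.0 s -> 60 bpm
  p <- mk_peaks(c(1.0, 0.8, 1.2))
  expect_equal(heart_rate(p), 60 / mean(p$rr_intervals))
  expect_equal(heart_rate(p), 60, tolerance = 0.02)

  empty <- structure(list(indices = integer(), rr_intervals = numeric(),
                          mean_rr = NA_real_, frame_rate = fs),
                     class = "peak_set")
  expect_error(heart_rate(empty), "fewer than 2 peaks")
})

test_that("the full chain recovers heart rate for cardiac-band pulses", {
  for (f0 in c(0.9, 1.6, 3.0)) {
    cfg <- synthetic_config(f0 = f0, seed = 100 + round(10 * f0))
    sess <- synthesize_session(cfg)
    v <- to_density(sess$bands)
    est <- wiener_matrix(
      build_pigment_autocorrelation(c(0.29, 0.31), 0.4, seed = 1),
      cfg$f, build_noise_autocorrelation(cfg$noise_sigma))
    x <- hemoglobin_signal(wiener_separate(est, v))
    hr <- heart_rate(detect_peaks(bandpass(detrend_smoothness_priors(x))))
    expect_lt(abs(hr - 60 * f0), 2)
  }
})
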