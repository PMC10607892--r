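fs <- 66.5

tone_mix <- function(amps, freqs, dur = 30, rate = fs) {
  t <- (seq_len(floor(dur * rate)) - 1) / rate
  x <- 0
  for (i in seq_along(amps)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  pulse_signal(x, rate)
}

test_that("spectral SNR reflects the band amplitude ratio", {
  # equal tones inside and outside the signal band -> 0 dB
  x <- tone_mix(c(1, 1), c(1, 20))
  expect_equal(snr_spectral(x), 0, tolerance = 0.1)

  # 10x amplitude ratio -> 20 dB
  x <- tone_mix(c(10, 1), c(1, 20))
  expect_equal(snr_spectral(x), 20, tolerance = 0.2)

  # amplitude and power modes agree
  expect_equal(snr_spectral(x, mode = "power"), snr_spectral(x),
               tolerance = 1e-9)

  # pure in-band tone, plain DFT of an integer number of periods: empty
  # noise band -> flagged unbounded
  t <- (0:2659) / 66.5  # 40 s, 1 Hz tone has integer periods
  pure <- pulse_signal(sin(2 * pi * t), 66.5)
  s <- snr_spectral(pure, window = "none")
  expect_true(is.infinite(s))
  expect_true(isTRUE(attr(s, "unbounded")))

  expect_error(snr_spectral(pulse_signal(rnorm(100), 20)), "Nyquist")
})

test_that("spectral SNR is invariant to amplitude scaling", {
  set.seed(10)
  x <- rnorm(2000)
  a <- snr_spectral(pulse_signal(x, fs))
  b <- snr_spectral(pulse_signal(100 * x, fs))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("correlation is the signed Pearson coefficient", {
  set.seed(11)
  a <- pulse_signal(rnorm(500), fs)
  expect_equal(pearson_correlation(a, a), 1)
  neg <- pulse_signal(-as.numeric(a), fs)
  expect_equal(pearson_correlation(a, neg), -1)

  b <- pulse_signal(rnorm(10000), fs)
  a2 <- pulse_signal(rnorm(10000), fs)
  expect_lt(abs(pearson_correlation(a2, b)), 0.05)

  const <- pulse_signal(rep(2, 500), fs)
  expect_error(pearson_correlation(a, const), "constant")
  expect_error(pearson_correlation(a, pulse_signal(rnorm(10), fs)),
               "equal length")
})

test_that("correlation is affine-invariant up to the sign of the scale", {
  set.seed(12)
  a <- pulse_signal(rnorm(300), fs)
  b <- pulse_signal(rnorm(300), fs)
  r <- pearson_correlation(a, b)
  b_aff <- pulse_signal(2.5 * as.numeric(b) + 7, fs)
  expect_equal(pearson_correlation(a, b_aff), r, tolerance = 1e-12)
  b_neg <- pulse_signal(-0.5 * as.numeric(b) + 1, fs)
  expect_equal(pearson_correlation(a, b_neg), -r, tolerance = 1e-12)
})

test_that("absolute error rate is the relative HR error in percent", {
  expect_equal(absolute_error_rate(72, 72), 0)
  expect_equal(absolute_error_rate(60, 66), 10)
  expect_equal(absolute_error_rate(80, 60), 25)
  expect_error(absolute_error_rate(0, 60), "hr_gt")
  # AER(h, h (1 + e)) = 100 |e|
  for (h in c(45, 60, 180)) {
    for (e in c(-0.3, -0.01, 0.02, 0.5)) {
      expect_equal(absolute_error_rate(h, h * (1 + e)), 100 * abs(e),
                   tolerance = 1e-10)
    }
  }
})

test_that("reference alignment resamples onto the camera grid", {
  # already at the target rate: values preserved
  set.seed(13)
  ref <- rnorm(300)
  out <- align_reference(ref, 66.5, 66.5, 300 / 66.5)
  expect_equal(as.numeric(out), ref[seq_along(out)], tolerance = 1e-9)

  out <- align_reference(rep(3, 100), 100, 66.5, 0.9)
  expect_true(all(out == 3))

  # 1 Hz sinusoid resampled 100 -> 66.5 Hz tracks the analytic waveform
  t_ref <- (0:2999) / 100
  out <- align_reference(sin(2 * pi * t_ref), 100, 66.5, 30)
  t_out <- (seq_along(out) - 1) / 66.5
  expect_gt(cor(as.numeric(out), sin(2 * pi * t_out)), 0.999)

  expect_error(align_reference(rnorm(50), 100, 66.5, 30), "shorter")
})

test_that("metrics report derives AER and serializes to a data frame", {
  rep1 <- metrics_report("wiener", "bandpassed", correlation = 0.9,
                         snr_db = 5, hr_estimated = 66, hr_reference = 60)
  expect_equal(rep1$aer_percent, 10)
  df <- as.data.frame(rep1)
  expect_identical(df$method, "wiener")
  expect_equal(df$aer_percent, 10)
  rep2 <- metrics_report("wiener", "raw", correlation = 0.2, snr_db = -1)
  expect_true(is.na(rep2$aer_percent))
})
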