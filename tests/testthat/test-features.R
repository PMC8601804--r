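test_that("time-domain features follow their defining formulas", {
  expect_equal(frame_magnitude(c(1, -1, 2)), 4)
  expect_equal(frame_magnitude(rep(0.5, 64)), 32)
  expect_equal(frame_magnitude(numeric(8)), 0)
  expect_equal(frame_average(c(1, -1, 2)), 2 / 3)
  expect_equal(frame_average(rep(3.5, 10)), 3.5)
  expect_equal(frame_variance(c(1, -1, 2)), 14 / 9)
  expect_equal(frame_variance(c(1, -1)), 1)
  expect_equal(frame_variance(rep(2, 5)), 0)
})

test_that("zero-crossing rate counts sign changes with zeros inheriting", {
  expect_equal(zero_crossing_rate(c(1, -1, 1, -1, 1)), 1)
  expect_equal(zero_crossing_rate(rep(2, 10)), 0)
  # one period of a sine at 8 samples: 0, +, +, +, 0, -, -, -
  expect_equal(zero_crossing_rate(sin(2 * pi * (0:7) / 8)), 2 / 7)
})

test_that("bandwidth matches the two-pass oracle and handles edge spectra", {
  s <- numeric(10); s[4] <- 2
  expect_equal(spectral_bandwidth(s), 0)
  s2 <- numeric(10); s2[c(1, 3)] <- 1   # bins 0 and 2 -> centroid 1, FB 1
  expect_equal(spectral_bandwidth(s2), 1)
  set.seed(5)
  for (i in 1:20) {
    r <- runif(129)
    expect_equal(spectral_bandwidth(r), bandwidth_oracle(r), tolerance = 1e-12)
  }
  expect_warning(z <- spectral_bandwidth(numeric(8)), "all-zero")
  expect_equal(z, 0)
})

test_that("peak/valley are logs of sorted-subband top/bottom means", {
  pv <- peak_valley(c(4, 3, 2, 1), subbands = list(1:4), alpha = 0.5)
  expect_equal(pv$peak, log(3.5))
  expect_equal(pv$valley, log(1.5))
  pv2 <- peak_valley(rep(2.5, 8), subbands = list(1:4, 5:8), alpha = 0.25)
  expect_equal(pv2$peak, c(log(2.5), log(2.5)))
  expect_equal(pv2$valley, pv2$peak)
  s <- runif(16)
  pv3 <- peak_valley(s, subbands = list(1:16), alpha = 1)
  expect_equal(pv3$peak, log(mean(s)))
  expect_equal(pv3$valley, log(mean(s)))
  expect_error(peak_valley(s, subbands = list(integer(0))), "empty")
  # all-zero magnitudes hit the log floor
  expect_equal(peak_valley(numeric(8), list(1:8), 0.5)$peak, log(1e-10))
})

test_that("default subbands partition the spectrum into log-spaced bands", {
  sb <- default_subbands(513, 4)
  expect_equal(length(sb), 4L)
  expect_equal(sort(unlist(sb)), 1:513)
  widths <- lengths(sb)
  expect_true(all(diff(widths) > 0))
})

test_that("autocorrelation pitch recovers pure tones and rejects noise", {
  expect_lt(abs(pitch_autocorr(make_tone(400, 44100, 4096), 44100) - 400), 4)
  expect_lt(abs(pitch_autocorr(make_tone(300, 16000, 4096), 16000) - 300), 3)
  # pulse train at 300 Hz
  pt <- numeric(4096); pt[seq(1, 4096, by = round(16000 / 300))] <- 1
  expect_lt(abs(pitch_autocorr(pt, 16000) - 300), 3)
  set.seed(17)
  expect_equal(pitch_autocorr(rnorm(4096), 16000), 0)
  expect_error(pitch_autocorr(make_tone(400, 16000, 100), 16000), "short")
})

test_that("pitch recovery stays within 1% median error at 20 dB SNR", {
  set.seed(23)
  f0s <- runif(100, 260, 590)
  err <- vapply(f0s, function(f0) {
    x <- make_tone(f0, 16000, 4096)
    x <- x + rnorm(4096, sd = sqrt(mean(x^2) / 10^(20 / 10)))
    abs(pitch_autocorr(x, 16000) - f0) / f0
  }, numeric(1L))
  expect_lt(median(err), 0.01)
})

test_that("LPC root-finding locates resonator frequencies", {
  set.seed(31)
  sr <- 16000
  x <- resonate(rnorm(8192), 1000, sr, r = 0.98)
  f <- formants_lpc(x[2049:6144], sr)
  expect_lt(abs(f[1] - 1000), 50)
  x2 <- resonate(rnorm(8192), c(800, 2400), sr, r = 0.98)
  f2 <- formants_lpc(x2[2049:6144], sr)
  expect_lt(abs(f2[1] - 800), 75)
  expect_lt(abs(f2[2] - 2400), 75)
  expect_warning(fz <- formants_lpc(numeric(512), sr), "degenerate")
  expect_equal(fz, numeric(6))
  # found formants are strictly increasing; absent ones are zero-padded
  nz <- f2[f2 > 0]
  expect_true(all(diff(nz) > 0))
})

test_that("cepstral recursion unrolls correctly and recovers AR models", {
  a1 <- 0.8
  cc <- lpc_to_cepstrum(c(a1), p = 2)
  expect_equal(cc, c(a1, a1^2 / 2))
  expect_warning(cz <- lpcc(numeric(256)), "degenerate")
  expect_equal(cz, numeric(12))

  set.seed(37)
  a_true <- c(0.75, -0.5)
  x <- make_ar(a_true, 4096)
  a_hat <- cryclass:::lpc_fit(x, 2, window = FALSE)
  expect_lt(max(abs(a_hat - a_true) / abs(a_true)), 0.05)
  expect_lt(max(abs(lpc_to_cepstrum(a_hat, 2) - lpc_to_cepstrum(a_true, 2)) /
                  abs(lpc_to_cepstrum(a_true, 2))), 0.05)
})

test_that("MFCCs match the textbook oracle and obey DCT invariances", {
  set.seed(41)
  sr <- 16000
  for (i in 1:5) {
    s <- runif(257)
    expect_equal(mfcc(s, sr), mfcc_oracle(s, sr), tolerance = 1e-8)
  }
  # flat filterbank energies live entirely in DCT coefficient 0
  fb <- mel_filterbank(257, sr, 26)
  flat <- rep(1, 26)
  expect_equal(cryclass:::dct_ortho(flat, 12), numeric(12), tolerance = 1e-12)
  # scaling spectrum power shifts only coefficient 0
  s <- runif(257) + 0.5
  expect_equal(mfcc(s, sr), mfcc(3 * s, sr), tolerance = 1e-10)
})

test_that("delta-MFCC is zero for constants and exact for linear ramps", {
  const <- matrix(2, nrow = 6, ncol = 3)
  expect_equal(delta_mfcc(const), matrix(0, 6, 3))
  ramp <- outer(1:10, c(1, -2, 0.5))
  d <- delta_mfcc(ramp, 2)
  for (j in 1:3) expect_equal(d[3:8, j], rep(c(1, -2, 0.5)[j], 6))
  single <- matrix(c(1, 2, 3), nrow = 1)
  expect_equal(delta_mfcc(single), matrix(0, 1, 3))
})

test_that("clip extraction reflects generator truth and is deterministic", {
  cfg <- synth_config("separable")
  g <- generate_clip(cfg, "sleep", seed = 77)
  ft <- extract_features(g$clip)
  expect_true(ft$pitch_mean > 270 & ft$pitch_mean < 340)
  expect_equal(ft$label, "sleep")
  ft2 <- extract_features(g$clip)
  expect_identical(ft, ft2)
  expect_error(extract_features(audio_clip(c(numeric(15999), 1e-4), 16000)),
               "no cry units")
})

test_that("time-domain features ignore FFT settings and vice versa", {
  cfg <- synth_config("separable")
  g <- generate_clip(cfg, "hunger", seed = 78)
  a <- extract_features(g$clip, feature_config(n_mels = 26))
  b <- extract_features(g$clip, feature_config(n_mels = 30))
  for (col in c("tm_mean", "ta_mean", "tv_mean", "tz_mean")) {
    expect_identical(a[[col]], b[[col]])
  }
  expect_false(identical(a$mfcc_01_mean, b$mfcc_01_mean))
})
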