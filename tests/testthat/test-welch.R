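test_that("Welch grid and scaling are correct", {
  sp <- welch_psd(noise_white(12000, 200, seed = 1))
  expect_equal(sp$freq[2] - sp$freq[1], 200 / 2048)
  expect_identical(sp$freq[1], 0)
  expect_equal(max(sp$freq), 100)
  expect_length(sp$freq, 1025)
  expect_true(all(sp$psd >= 0))
  expect_identical(sp$settings$n_segments, 10L)

  # Parseval: integrated PSD approximates the time-domain variance
  w <- noise_white(12000, 200, sd = 1, seed = 2)
  spw <- welch_psd(w)
  expect_lt(abs(sum(spw$psd) * (200 / 2048) / var(w$samples) - 1), 0.05)

  # pure tone peaks at the nearest grid frequency
  t <- (0:11999) / 200
  tone <- welch_psd(eeg_channel(sin(2 * pi * 10 * t), 200))
  fpk <- tone$freq[which.max(tone$psd)]
  expect_equal(fpk, tone$freq[which.min(abs(tone$freq - 10))])

  expect_error(welch_psd(noise_white(1000, 200, seed = 1)), "2048")
})

test_that("Welch output matches the independent reference implementation", {
  # frozen from scipy.signal.welch (hamming, nperseg = nfft = 256, 50%
  # overlap, constant detrend, density scaling) on a deterministic signal
  i <- 1:600
  x <- sin(0.1 * i) + 0.5 * cos(0.017 * i) + 0.25 * sin(0.9 * i)
  sp <- welch_psd(x, nperseg = 256, fs = 200)
  ref <- c(9.0494037484588497e-03, 7.1308621074282333e-02,
           1.1077913057479043e-01, 1.5622058378786528e-06,
           2.5781179928090134e-07, 1.2178656871407805e-07,
           1.0592577634083603e-07, 5.2953756664419004e-08)
  expect_equal(sp$psd[c(1, 2, 6, 33, 65, 101, 128, 129)], ref, tolerance = 1e-10)
  expect_equal(sum(sp$psd), 0.7655701728600667, tolerance = 1e-10)
  expect_equal(sp$freq[c(2, 129)], c(0.78125, 100))
})

test_that("estimator variance shrinks with the number of segments", {
  set.seed(5)
  one_bin_var <- function(n) {
    ps <- replicate(60, {
      sp <- welch_psd(rnorm(n), nperseg = 512, fs = 200)
      mean(sp$psd[100:150])
    })
    var(ps)
  }
  v_few <- one_bin_var(1024)    # 3 segments at 50% overlap
  v_many <- one_bin_var(8192)   # 31 segments
  expect_gt(v_few / v_many, 4)  # ~10x expected; demand a clear drop
})

test_that("PSD scales quadratically with signal amplitude", {
  x <- noise_white(4000, 200, seed = 3)
  sp1 <- welch_psd(x)
  sp2 <- welch_psd(eeg_channel(2 * x$samples, 200))
  expect_equal(sp2$psd, 4 * sp1$psd, tolerance = 1e-12)
})

test_that("band slicing uses the closed interval and never the DC bin", {
  sp <- welch_psd(noise_white(12000, 200, seed = 1))
  lo <- band_slice(sp, band_low())
  # bins k = 6..40 of df = 200/2048 lie in [0.5, 4]
  expect_length(lo$freq, 35)
  expect_equal(min(lo$freq), 6 * 200 / 2048)
  expect_equal(max(lo$freq), 40 * 200 / 2048)
  expect_true(all(lo$freq >= 0.5 & lo$freq <= 4))

  full <- band_slice(sp, band(1e-9 + 0, 100))
  expect_length(full$freq, 1024)         # everything except DC

  expect_gt(length(band_slice(sp, band(90, 99))$freq), 0)
  expect_error(band_slice(sp, band(0.45, 0.46)), "no bins")
  expect_error(band_slice(sp, band(50, 120)), "exceeds")
  expect_error(band(4, 0.5), "f_hi")
})

test_that("mean band power averages and normalizes as defined", {
  flat <- fake_spectrum(function(f) rep(3.5, length(f)))
  expect_equal(mean_band_power(flat, band(1, 50), normalize = "none")$value, 3.5)

  # unit-total normalization makes the spectrum integrate to 1
  shaped <- fake_spectrum(function(f) pmax(f, 0.1)^-1.3)
  df <- shaped$freq[2] - shaped$freq[1]
  norm_psd <- shaped$psd / (sum(shaped$psd[shaped$freq > 0]) * df)
  expect_equal(sum(norm_psd[shaped$freq > 0]) * df, 1, tolerance = 1e-9)

  # analytic quadrature check for a 1/f^2 spectrum over 33-80 Hz
  inv2 <- fake_spectrum(function(f) ifelse(f > 0, f^-2, 1))
  got <- mean_band_power(inv2, band_high(), normalize = "none")$value
  grid_f <- inv2$freq[inv2$freq >= 33 & inv2$freq <= 80]
  expect_equal(got, mean(grid_f^-2), tolerance = 1e-6)

  # band_slice-then-mean equals the masked mean on the full spectrum
  sp <- welch_psd(noise_powerlaw(8000, 200, beta = 1, seed = 9))
  expect_identical(mean(band_slice(sp, band_high())$psd),
                   masked_band_mean(sp$freq, sp$psd, 33, 80))

  zero <- fake_spectrum(function(f) rep(0, length(f)))
  expect_error(mean_band_power(zero, band(1, 50)), "zero")
})
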