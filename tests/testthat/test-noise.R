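test_that("white noise matches its generating distribution and degenerate cases", {
  w <- noise_white(12000, fs = 200, mean = 0, sd = 1, seed = 1)
  expect_s3_class(w, "eeg_channel")
  expect_length(w$samples, 12000)
  expect_lt(abs(mean(w$samples)), 4 / sqrt(12000))
  expect_lt(abs(sd(w$samples) - 1), 0.05)

  const <- noise_white(100, fs = 200, mean = 3, sd = 0, seed = 2)
  expect_identical(const$samples, rep(3, 100))

  expect_error(noise_white(1, fs = 200), "n_samples")
  expect_error(noise_white(100, fs = -1), "fs")
  expect_error(noise_white(100, fs = 200, sd = -1), "sd")
})

test_that("Brownian noise is the cumulative sum of the white increments", {
  b <- noise_brownian(5000, fs = 200, mean = 2, sd = 1.3, seed = 7)
  w <- noise_white(5000, fs = 200, mean = 0, sd = 1.3, seed = 7)
  # differencing recovers the underlying white sequence
  expect_equal(diff(b$samples), w$samples[-1], tolerance = 1e-9)
  expect_identical(b$samples[1], 2 + w$samples[1])
  expect_identical(b$samples, 2 + cumsum(w$samples))
})

test_that("Brownian ensemble variance grows linearly with sample index", {
  set.seed(42)
  n <- 400
  ens <- replicate(200, noise_brownian(n, fs = 200, seed = NULL)$samples)
  v <- apply(ens, 1, var)
  k <- seq_len(n)
  r2 <- summary(lm(v ~ k))$r.squared
  expect_gt(r2, 0.95)
})

test_that("spectral-synthesis noise recovers its target exponent (periodogram oracle)", {
  for (b in c(0.5, 1, 1.5, 2)) {
    sl <- vapply(1:50, function(i)
      -periodogram_slope(noise_powerlaw(12000, 200, beta = b,
                                        seed = 1000 * b + i)$samples, 200),
      numeric(1))
    expect_lt(abs(mean(sl) - b), 0.1)
  }
})

test_that("beta = 0 synthesis is statistically indistinguishable from white noise", {
  s_pl <- vapply(1:50, function(i)
    periodogram_slope(noise_powerlaw(2000, 200, beta = 0, seed = 100 + i)$samples, 200),
    numeric(1))
  s_wh <- vapply(1:50, function(i)
    periodogram_slope(noise_white(2000, 200, seed = 500 + i)$samples, 200),
    numeric(1))
  expect_gt(t.test(s_pl, s_wh)$p.value, 0.01)
})

test_that("beta = 2 synthesis and Brownian noise agree in the low band", {
  # the discrete random-walk spectrum is 1/(4 sin^2(w/2)): ~1/f^2 only at
  # low frequency, so the cross-generator comparison is made there
  lowfit <- function(ch) abs(specslope(ch, band = band_low())$beta)
  b_pl <- vapply(1:10, function(i)
    lowfit(noise_powerlaw(12000, 200, beta = 2, seed = 10 + i)), numeric(1))
  b_br <- vapply(1:10, function(i)
    lowfit(noise_brownian(12000, 200, seed = 30 + i)), numeric(1))
  expect_lt(abs(mean(b_pl) - mean(b_br)), 0.1)
})

test_that("exponent estimates approach 0 (white) and ~2 (Brownian) as n grows", {
  bias_w <- bias_b <- numeric(3)
  ns <- c(2e3, 2e4, 2e5)
  for (i in seq_along(ns)) {
    bias_w[i] <- abs(mean(vapply(1:3, function(j)
      -periodogram_slope(noise_white(ns[i], 200, seed = i * 10 + j)$samples, 200),
      numeric(1))))
    # low-frequency fifth of the periodogram, where 1/(4sin^2) ~ 1/w^2
    bias_b[i] <- abs(mean(vapply(1:3, function(j) {
      ch <- noise_brownian(ns[i], 200, seed = i * 50 + j)
      abs(specslope(ch, band = band(0.5, 20), nperseg = min(2048, ns[i]))$beta)
    }, numeric(1))) - 2)
  }
  expect_true(all(diff(bias_w) < 0.05))   # non-increasing up to noise
  expect_lt(bias_w[3], bias_w[1])
  expect_lt(bias_b[3], bias_b[1])
})

test_that("fitted exponent is monotone in the target exponent", {
  grid <- c(0, 0.5, 1, 1.5, 2, 2.5)
  means <- vapply(grid, function(b) {
    mean(vapply(1:8, function(i)
      -periodogram_slope(noise_powerlaw(6000, 200, beta = b,
                                        seed = b * 777 + i)$samples, 200),
      numeric(1)))
  }, numeric(1))
  expect_identical(cor(means, grid, method = "spearman"), 1)
})

test_that("oscillatory peak raises PSD locally and conserves the background", {
  x <- noise_powerlaw(12000, 200, beta = 1, seed = 5)
  xp <- add_peak(x, center_freq = 10, bandwidth = 2, amplitude = 10, seed = 6)

  sp0 <- welch_psd(x); sp1 <- welch_psd(xp)
  # peak body exceeds the log-linear interpolation of the background
  bg_at <- function(sp, f) approx(sp$freq, log10(sp$psd), f)$y
  interp_9_11 <- 10^approx(log10(c(4, 20)), c(bg_at(sp0, 4), bg_at(sp0, 20)),
                           log10(c(9, 10, 11)))$y
  expect_gt(masked_band_mean(sp1$freq, sp1$psd, 9, 11), mean(interp_9_11))

  # background conserved outside [center - 2 bw, center + 2 bw]
  out <- sp0$freq > 0 & (sp0$freq < 6 | sp0$freq > 14)
  expect_lt(abs(mean(sp1$psd[out]) / mean(sp0$psd[out]) - 1), 0.05)

  # amplitude 0 is the identity
  expect_identical(add_peak(x, amplitude = 0), x)
  expect_error(add_peak(x, center_freq = 120), "center_freq")
})

test_that("generators are bit-identical under a fixed seed and leave the RNG alone", {
  set.seed(99); before <- .Random.seed
  a <- noise_powerlaw(1000, 200, beta = 1.2, seed = 11)
  expect_identical(.Random.seed, before)
  b <- noise_powerlaw(1000, 200, beta = 1.2, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(noise_white(500, 200, seed = 3)$samples,
                   noise_white(500, 200, seed = 3)$samples)
  expect_identical(noise_brownian(500, 200, seed = 3)$samples,
                   noise_brownian(500, 200, seed = 3)$samples)
})
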