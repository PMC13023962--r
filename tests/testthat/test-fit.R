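test_that("log-log transform is exact and propagates uncertainties", {
  sp <- fake_spectrum(function(f) ifelse(f > 0, f^-2, 1))
  pts <- to_loglog(sp, band(1, 50))
  # exactly collinear with slope -2
  slopes <- diff(pts$y) / diff(pts$x)
  expect_equal(slopes, rep(-2, length(slopes)), tolerance = 1e-12)

  # sigma = psd * ln 10  =>  dy = 1 for every bin
  pts2 <- to_loglog(sp, band(1, 50), sigma = band_slice(sp, band(1, 50))$psd * log(10))
  expect_equal(pts2$dy, rep(1, nrow(pts2)), tolerance = 1e-12)
  expect_equal(pts2$w, rep(1, nrow(pts2)), tolerance = 1e-12)

  neg <- fake_spectrum(function(f) rep(1, length(f)))
  neg$psd[50] <- 0
  expect_error(to_loglog(neg, band(1, 50)), "non-positive")
})

test_that("replicate white-noise SD gives near-constant log-domain uncertainty", {
  set.seed(11)
  ps <- replicate(50, welch_psd(rnorm(4000), nperseg = 512, fs = 200)$psd)
  m <- rowMeans(ps); s <- apply(ps, 1, sd)
  keep <- 2:257
  dy <- s[keep] / (m[keep] * log(10))
  expect_lt(sd(dy) / mean(dy), 0.25)     # flat to sampling noise
})

test_that("weighted least squares is exact on a line and equals OLS under equal weights", {
  x <- seq(0, 2, by = 0.25)
  y <- 3 - 2 * x
  f <- wls_fit(x, y, w = c(5, rep(1, 7), 9))
  expect_equal(f$beta, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 3, tolerance = 1e-12)
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  set.seed(21)
  xr <- runif(12); yr <- rnorm(12)
  fw <- wls_fit(xr, yr, w = rep(2.5, 12))
  ref <- ols_closed_form(xr, yr)
  expect_equal(fw$intercept, unname(ref["intercept"]), tolerance = 1e-12)
  expect_equal(-fw$beta, unname(ref["slope"]), tolerance = 1e-12)
})

test_that("weighted fit matches the brute-force grid minimizer", {
  # a small heteroscedastic configuration with block weights
  x <- c(0, 0.5, 1, 1.5, 2)
  y <- c(1.1, 0.4, -0.2, -1.2, -1.7)
  w <- c(1, 1, 4, 4, 4)
  f <- wls_fit(x, y, w)
  g <- grid_wls(x, y, w)
  expect_equal(f$intercept, unname(g["intercept"]), tolerance = 1e-6)
  expect_equal(-f$beta, unname(g["slope"]), tolerance = 1e-6)

  # property-style: random small instances
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    x <- sort(runif(n, -1, 2))
    y <- rnorm(n, 1 - 1.5 * x, 0.4)
    w <- runif(n, 0.2, 5)
    f <- wls_fit(x, y, w)
    g <- grid_wls(x, y, w)
    expect_equal(f$intercept, unname(g["intercept"]), tolerance = 1e-6)
    expect_equal(-f$beta, unname(g["slope"]), tolerance = 1e-6)
  }

  expect_error(wls_fit(c(1, 2), c(1, 2)), "3 points")
  expect_error(wls_fit(1:4, 1:4, w = c(1, 1, 0, 1)), "positive")
})

test_that("the exponent is invariant to PSD scale and to the log base", {
  sp <- welch_psd(noise_powerlaw(8000, 200, beta = 1.3, seed = 41))
  f1 <- specslope(sp, band = band_low())
  sp7 <- sp; sp7$psd <- 7.3 * sp$psd
  f2 <- specslope(sp7, band = band_low())
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f2$intercept - f1$intercept, log10(7.3), tolerance = 1e-9)

  # natural-log pipeline recovers the identical exponent
  pts <- to_loglog(sp, band_low())
  fit_e <- lm(log(pts$psd) ~ log(pts$freq))
  expect_equal(-unname(coef(fit_e)[2]), f1$beta, tolerance = 1e-9)
})

test_that("specslope methods are coherent", {
  ch <- noise_powerlaw(8000, 200, beta = 1.5, seed = 51)
  f <- specslope(ch, band = band_low(), filter = filter_spec("lowpass"))
  expect_s3_class(f, "specslope")
  expect_identical(unname(coef(f)["beta"]), f$beta)
  expect_equal(predict(f, freq = 1), f$intercept, tolerance = 1e-12)
  expect_equal(predict(f, freq = 10, type = "psd"),
               10^(f$intercept - f$beta), tolerance = 1e-12)
  ci <- confint(f)
  expect_lt(ci["beta", 1], abs(f$beta))
  expect_gt(ci["beta", 2], abs(f$beta))
  expect_length(residuals(f), f$n_points)
  expect_output(print(summary(f)), "CI for \\|beta\\|")

  sims <- simulate(f, nsim = 2, seed = 9, n_samples = 2000)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "eeg_channel")

  # a filtered deep-stopband band with compensation still errors cleanly if
  # the PSD underflows to non-positive values
  expect_error(specslope(ch, band = band(0.5, 4), filter = NULL,
                         nperseg = 10000, nfft = 12000), "nperseg")
})

test_that("min-max exponent map normalizes and rejects degenerate input", {
  db <- delta_beta(c(A = 1, B = 2, C = 3))
  expect_equal(as.numeric(db), c(0, 0.5, 1))
  expect_identical(names(db), c("A", "B", "C"))

  set.seed(61)
  v <- rnorm(8, 2, 0.5); names(v) <- letters[1:8]
  dv <- delta_beta(v)
  expect_true(all(dv >= 0 & dv <= 1))
  expect_identical(min(dv), 0)
  expect_identical(max(dv), 1)

  expect_error(delta_beta(c(A = 2, B = 2)), "degenerate")
  expect_error(delta_beta(c(A = 2)), "2 regions")
})
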