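# Colored-noise simulators.
#
# White noise is drawn directly; Brownian noise is the cumulative sum of
# white increments; arbitrary-exponent noise is synthesized spectrally:
# the one-sided amplitude spectrum is shaped as f^(-beta/2) (so the
# expected PSD is proportional to f^-beta), phases are i.i.d. uniform, and
# the signal is obtained by inverse FFT. The spectral route gives the
# exact expected spectrum by construction, which keeps recovery oracles
# simple.

# inverse-FFT synthesis from a one-sided magnitude shape; shape is a
# function of frequency (Hz, > 0) returning PSD-shape values (any scale)
synth_colored <- function(n, fs, shape) {
  nh <- n %/% 2L
  f <- seq_len(nh) * fs / n
  amp <- sqrt(shape(f))                      # amplitude = sqrt(PSD shape)
  ph <- stats::runif(nh, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  if (n %% 2L == 0L) {
    spec[nh] <- Re(spec[nh])                 # Nyquist bin must be real
    full <- c(0, spec, Conj(rev(spec[-nh])))
  } else {
    full <- c(0, spec, Conj(rev(spec)))
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

validate_noise_args <- function(n_samples, fs, sd) {
  check_scalar(n_samples, "n_samples", lower = 2, integer = TRUE)
  check_scalar(fs, "fs")
  if (fs <= 0) stop_field("fs", "must be > 0")
  check_scalar(sd, "sd", lower = 0)
}

#' Simulate Gaussian white noise
#'
#' Independent normal samples with the given mean and standard deviation.
#' White noise has a flat power spectrum: its log-log spectral slope is
#' zero, making it the first reference signal for exponent estimation.
#'
#' @param n_samples number of samples (default one minute at 200 Hz, the
#'   standard resting-state recording format handled by this package).
#' @param fs sampling rate, Hz.
#' @param mean,sd mean and standard deviation of the samples (signal units).
#' @param seed optional non-negative integer; a fixed seed gives
#'   bit-identical output and leaves the caller's RNG state untouched.
#' @param ... metadata passed to [eeg_channel()] (e.g. `subject_id`).
#' @return an [eeg_channel()].
#' @seealso [noise_brownian()], [noise_powerlaw()], [add_peak()]
#' @examples
#' w <- noise_white(2000, fs = 200, seed = 1)
#' sd(w$samples)
#' @export
noise_white <- function(n_samples = 12000, fs = 200, mean = 0, sd = 1,
                        seed = NULL, ...) {
  validate_noise_args(n_samples, fs, sd)
  x <- with_seed(seed, stats::rnorm(n_samples, mean, sd))
  eeg_channel(x, fs, history = "noise_white", ...)
}

#' Simulate Brownian noise (integrated white noise)
#'
#' Cumulative sum of zero-mean i.i.d. Gaussian increments of standard
#' deviation `sd`, shifted by `mean`. Its theoretical power spectrum falls
#' as 1/f^2; the finite-sample Welch estimate of the slope magnitude is
#' slightly below 2 because window leakage flattens steep spectra (see the
#' methods vignette). The increments are drawn exactly as
#' `noise_white(mean = 0, sd = sd, seed = seed)`, so differencing the
#' output reproduces the underlying white sequence sample for sample.
#'
#' No 1/sqrt(n) normalization is applied to the cumulative sum: the
#' log-log slope is invariant under rescaling, so the exponent is
#' unaffected.
#'
#' @inheritParams noise_white
#' @param sd standard deviation of the generating increments.
#' @return an [eeg_channel()].
#' @examples
#' b <- noise_brownian(2000, fs = 200, seed = 1)
#' w <- noise_white(2000, fs = 200, sd = 1, seed = 1)
#' all.equal(diff(b$samples), w$samples[-1])
#' @export
noise_brownian <- function(n_samples = 12000, fs = 200, mean = 0, sd = 1,
                           seed = NULL, ...) {
  validate_noise_args(n_samples, fs, sd)
  w <- with_seed(seed, stats::rnorm(n_samples, 0, sd))
  eeg_channel(mean + cumsum(w), fs, history = "noise_brownian", ...)
}

#' Simulate noise with an arbitrary spectral exponent
#'
#' Synthesizes a signal whose expected one-sided power spectral density is
#' proportional to f^(-beta) over (0, fs/2], by shaping the amplitude
#' spectrum of white noise as f^(-beta/2) with independent uniform random
#' phases and inverse-transforming. The DC component is zero and the
#' output is rescaled to standard deviation `sd` (then shifted by
#' `mean`). `beta = 0` is white noise; `beta = 2` matches Brownian noise
#' in expectation.
#'
#' When `beta_high` is supplied the spectrum is piecewise: exponent
#' `beta` below `f_break` and `beta_high` above it, continuous at the
#' break. This is how cohort channels with band-specific exponents are
#' produced.
#'
#' @inheritParams noise_white
#' @param beta target spectral exponent (dimensionless, >= 0).
#' @param beta_high optional second exponent applied above `f_break`.
#' @param f_break break frequency (Hz) separating the two power-law
#'   segments; default `sqrt(4 * 33)`, the geometric midpoint of the two
#'   analysis bands.
#' @return an [eeg_channel()].
#' @examples
#' x <- noise_powerlaw(4000, fs = 200, beta = 1.5, seed = 2)
#' @export
noise_powerlaw <- function(n_samples = 12000, fs = 200, beta, mean = 0,
                           sd = 1, seed = NULL, beta_high = NULL,
                           f_break = sqrt(4 * 33), ...) {
  validate_noise_args(n_samples, fs, sd)
  check_scalar(beta, "beta", lower = 0)
  check_scalar(beta_high, "beta_high", lower = 0, allow_null = TRUE)
  shape <- if (is.null(beta_high)) {
    function(f) f^(-beta)
  } else {
    check_scalar(f_break, "f_break", lower = 0)
    function(f) ifelse(f <= f_break, f^(-beta),
                       f_break^(beta_high - beta) * f^(-beta_high))
  }
  x <- with_seed(seed, synth_colored(n_samples, fs, shape))
  s <- stats::sd(x)
  if (s > 0) x <- x / s * sd
  eeg_channel(mean + x, fs, history = "noise_powerlaw", ...)
}

#' Superimpose a narrowband oscillatory peak
#'
#' Adds an oscillation to a channel as an exact Gaussian bump in the
#' frequency domain: the added component's one-sided PSD is
#' `amplitude * S0 * exp(-(f - center_freq)^2 / (2 s^2))`, where `S0` is
#' the channel's estimated background PSD at `center_freq` and `s` is the
#' Gaussian SD corresponding to a full width at half maximum of
#' `bandwidth`. The component is synthesized with random phases and added
#' in the time domain; outside the peak neighbourhood the background
#' spectrum is conserved. This emulates the alpha (8-12 Hz) and similar
#' oscillatory peaks that ride on the aperiodic background of neural
#' recordings and bias naive slope fits.
#'
#' @param ts an [eeg_channel()].
#' @param center_freq peak centre frequency, Hz; must lie below fs/2.
#' @param bandwidth full width at half maximum of the spectral bump, Hz.
#' @param amplitude peak PSD relative to the background PSD at
#'   `center_freq` (dimensionless, >= 0); `0` returns the input unchanged.
#' @param seed optional integer seed for the component's random phases.
#' @return an [eeg_channel()] with the oscillation added.
#' @examples
#' x <- noise_powerlaw(4000, fs = 200, beta = 1, seed = 3)
#' xa <- add_peak(x, center_freq = 10, bandwidth = 2, amplitude = 10, seed = 4)
#' @export
add_peak <- function(ts, center_freq = 10, bandwidth = 2, amplitude = 10,
                     seed = NULL) {
  ts <- as_channel(ts)
  check_scalar(center_freq, "center_freq", lower = 0)
  if (center_freq <= 0 || center_freq >= ts$fs / 2)
    stop_field("center_freq", sprintf("must lie in (0, fs/2) = (0, %g)", ts$fs / 2))
  check_scalar(bandwidth, "bandwidth")
  if (bandwidth <= 0) stop_field("bandwidth", "must be > 0")
  check_scalar(amplitude, "amplitude", lower = 0)
  if (amplitude == 0) return(ts)

  n <- length(ts$samples)
  sp <- welch_psd(ts, nperseg = min(2048L, n))
  s0 <- stats::approx(sp$freq, sp$psd, xout = center_freq)$y
  sdev <- bandwidth / (2 * sqrt(2 * log(2)))
  bump <- with_seed(seed, synth_colored(n, ts$fs, function(f) {
    # PSD -> squared DFT magnitude scale: |X_k|^2 = S(f) * fs * n / 2
    amplitude * s0 * exp(-(f - center_freq)^2 / (2 * sdev^2)) * ts$fs * n / 2
  }))
  out <- ts
  out$samples <- ts$samples + bump
  out$history <- c(ts$history, sprintf("add_peak(%g Hz)", center_freq))
  out
}
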