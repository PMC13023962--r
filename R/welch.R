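# Welch power spectral density estimation and band utilities.

# periodic (DFT-even) window, the convention of standard spectral
# estimators; negligible difference from the symmetric form at n = 2048
make_window <- function(name, n) {
  k <- 0:(n - 1)
  switch(name,
    hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
    hann    = 0.5 - 0.5 * cos(2 * pi * k / n),
    boxcar  = rep(1, n),
    stop_field("window", sprintf("unknown window '%s'", name)))
}

#' Welch power spectral density estimate
#'
#' One-sided, density-scaled PSD averaged over windowed overlapping
#' segments. Defaults follow the analysis this package implements: a
#' Hamming window with a 2048-point FFT (10.24 s segments at 200 Hz,
#' frequency resolution fs/2048), 50% overlap, and per-segment mean
#' removal.
#'
#' @param ts an [eeg_channel()] or numeric vector (then supply `fs`).
#' @param nperseg samples per segment; the signal must be at least this
#'   long.
#' @param nfft FFT length (>= `nperseg`; zero-padded beyond `nperseg`).
#' @param overlap fractional overlap between consecutive segments in
#'   `[0, 1)`.
#' @param window window name: `"hamming"` (default), `"hann"` or
#'   `"boxcar"`.
#' @param detrend `"constant"` (subtract each segment's mean, default) or
#'   `"none"`.
#' @param fs sampling rate, required only for numeric input.
#' @return an object of class `spectrum_estimate`: list with `freq`
#'   (ascending Hz grid from 0 to fs/2, spacing fs/nfft), `psd`
#'   (signal-units^2/Hz), `fs`, `settings` and `meta` (subject, region,
#'   channel, filter history).
#' @examples
#' sp <- welch_psd(noise_white(4000, fs = 200, seed = 1), nperseg = 1024)
#' # total power approximates the time-domain variance
#' sum(sp$psd) * (200 / 1024)
#' @export
welch_psd <- function(ts, nperseg = 2048, nfft = nperseg, overlap = 0.5,
                      window = "hamming", detrend = c("constant", "none"),
                      fs = NULL) {
  ts <- as_channel(ts, fs)
  detrend <- match.arg(detrend)
  check_scalar(nperseg, "nperseg", lower = 8, integer = TRUE)
  check_scalar(nfft, "nfft", lower = nperseg, integer = TRUE)
  check_scalar(overlap, "overlap", lower = 0)
  if (overlap >= 1) stop_field("overlap", "must be < 1")
  x <- ts$samples
  n <- length(x)
  if (n < nperseg)
    stop(sprintf("signal too short for Welch estimate: %d samples, need >= %d (nperseg)",
                 n, nperseg), call. = FALSE)
  nperseg <- as.integer(nperseg); nfft <- as.integer(nfft)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  w <- make_window(window, nperseg)
  u <- sum(w^2)                                # window power normalization
  nbin <- nfft %/% 2L + 1L
  acc <- numeric(nbin)
  pad <- numeric(nfft - nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (detrend == "constant") seg <- seg - mean(seg)
    X <- stats::fft(c(seg * w, pad))
    p <- Mod(X[seq_len(nbin)])^2 / (ts$fs * u)
    p[2:(nbin - 1L)] <- 2 * p[2:(nbin - 1L)]   # one-sided (DC/Nyquist once)
    acc <- acc + p
  }
  structure(
    list(freq = (0:(nbin - 1L)) * ts$fs / nfft,
         psd = acc / length(starts),
         fs = ts$fs,
         settings = list(nperseg = nperseg, nfft = nfft, overlap = overlap,
                         window = window, detrend = detrend,
                         n_segments = length(starts)),
         meta = list(subject_id = ts$subject_id, region = ts$region,
                     channel_id = ts$channel_id, history = ts$history)),
    class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d bins, 0-%g Hz (df = %.5g Hz), %s window, %d segment(s)\n",
              length(x$freq), max(x$freq), x$freq[2] - x$freq[1],
              x$settings$window, x$settings$n_segments))
  invisible(x)
}

#' @export
plot.spectrum_estimate <- function(x, ..., log = "xy") {
  keep <- x$freq > 0 & x$psd > 0
  graphics::plot(x$freq[keep], x$psd[keep], type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "PSD (units²/Hz)", ...)
  invisible(x)
}

#' Frequency band
#'
#' A closed frequency interval on the spectral grid. The two analysis
#' bands of the pipeline are provided as constructors: [band_low()]
#' (0.5-4 Hz) and [band_high()] (33-80 Hz).
#'
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @param name optional label.
#' @return an object of class `freq_band`.
#' @export
band <- function(f_lo, f_hi, name = sprintf("%g-%g Hz", f_lo, f_hi)) {
  check_scalar(f_lo, "f_lo"); check_scalar(f_hi, "f_hi")
  if (f_lo <= 0) stop_field("f_lo", "must be > 0")
  if (f_hi <= f_lo) stop_field("f_hi", "must be > f_lo")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "freq_band")
}

#' @rdname band
#' @export
band_low <- function() band(0.5, 4, "low")

#' @rdname band
#' @export
band_high <- function() band(33, 80, "high")

#' @export
print.freq_band <- function(x, ...) {
  cat(sprintf("<freq_band> %s [%g, %g] Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Restrict a spectrum to a band
#'
#' Keeps the bins with `f_lo <= f <= f_hi` (closed interval, boundary
#' bins included). The DC bin is never included.
#'
#' @param sp a `spectrum_estimate`.
#' @param bd a [band()].
#' @return a `spectrum_estimate` on the restricted grid.
#' @export
band_slice <- function(sp, bd) {
  stopifnot(inherits(sp, "spectrum_estimate"), inherits(bd, "freq_band"))
  if (bd$f_hi > max(sp$freq) + 1e-9)
    stop_field("band", sprintf("f_hi = %g exceeds the spectrum's maximum %g Hz",
                               bd$f_hi, max(sp$freq)))
  keep <- sp$freq > 0 & sp$freq >= bd$f_lo & sp$freq <= bd$f_hi
  if (!any(keep))
    stop(sprintf("band [%g, %g] Hz selects no bins (df = %g Hz)",
                 bd$f_lo, bd$f_hi, sp$freq[2] - sp$freq[1]), call. = FALSE)
  out <- sp
  out$freq <- sp$freq[keep]
  out$psd <- sp$psd[keep]
  out$settings$band <- bd$name
  out
}

#' Mean (normalized) band power
#'
#' Arithmetic mean of the PSD over a band's bins. With
#' `normalize = "unit_total"` the spectrum is first divided by its total
#' power over (0, fs/2] (so spectra integrate to one before averaging);
#' this is the gamma-band summary used when relating band power to the
#' spectral exponent across regions.
#'
#' @inheritParams band_slice
#' @param normalize `"unit_total"` or `"none"`.
#' @return a list of class `band_power` with `value`, `band` and
#'   `normalize`.
#' @export
mean_band_power <- function(sp, bd, normalize = c("unit_total", "none")) {
  stopifnot(inherits(sp, "spectrum_estimate"))
  normalize <- match.arg(normalize)
  psd <- sp$psd
  if (normalize == "unit_total") {
    df <- sp$freq[2] - sp$freq[1]
    tot <- sum(psd[sp$freq > 0]) * df
    if (tot <= 0) stop("total power is zero; cannot normalize", call. = FALSE)
    psd <- psd / tot
  }
  spn <- sp
  spn$psd <- psd
  sl <- band_slice(spn, bd)
  structure(list(value = mean(sl$psd), band = bd, normalize = normalize),
            class = "band_power")
}

#' Export a spectrum as CSV with a JSON settings sidecar
#'
#' Writes `freq_hz,psd` columns to `path` and the estimation settings and
#' source metadata to `<path>.json`.
#'
#' @param sp a `spectrum_estimate`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum_estimate"))
  utils::write.csv(data.frame(freq_hz = sp$freq, psd = sp$psd),
                   path, row.names = FALSE)
  jsonlite::write_json(list(settings = sp$settings, meta = sp$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}
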