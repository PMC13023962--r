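#' Butterworth filter specification
#'
#' Describes the band-isolation filters used before exponent estimation:
#' by default a 7th-order low-pass with an 8 Hz cutoff (isolating the
#' 0.5-4 Hz scale-free band while suppressing the alpha peak) or a
#' 7th-order high-pass with a 33 Hz cutoff (isolating the 33-80 Hz band).
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff -3 dB cutoff frequency in Hz; defaults to 8 for lowpass
#'   and 33 for highpass.
#' @param order filter order (positive integer, default 7).
#' @param zero_phase logical; apply the filter forward and backward
#'   (default). Zero-phase filtering has no phase lag and a squared
#'   magnitude response.
#' @return an object of class `filter_spec`.
#' @seealso [apply_filter()], [butter_gain()]
#' @export
filter_spec <- function(kind = c("lowpass", "highpass"), cutoff = NULL,
                        order = 7, zero_phase = TRUE) {
  kind <- match.arg(kind)
  cutoff <- cutoff %||% if (kind == "lowpass") 8 else 33
  check_scalar(cutoff, "cutoff")
  if (cutoff <= 0) stop_field("cutoff", "must be > 0")
  check_scalar(order, "order", lower = 1, integer = TRUE)
  stopifnot(is.logical(zero_phase), length(zero_phase) == 1L)
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order),
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s Butterworth, order %d, cutoff %g Hz%s\n",
              x$kind, x$order, x$cutoff,
              if (x$zero_phase) ", zero-phase" else ""))
  invisible(x)
}

#' Butterworth magnitude response
#'
#' The single-pass analog Butterworth magnitude,
#' `1 / sqrt(1 + (f/fc)^(2n))` for a low-pass and
#' `1 / sqrt(1 + (fc/f)^(2n))` for a high-pass filter (gain 1/sqrt(2),
#' i.e. -3.01 dB, at the cutoff). With `fs` supplied, the exact frequency
#' response magnitude of the digital (bilinear-transform) filter actually
#' applied by [apply_filter()] is returned instead; the two agree closely
#' except near the Nyquist frequency, where bilinear warping matters.
#'
#' @param spec a [filter_spec()].
#' @param freq frequencies in Hz (vectorized, >= 0).
#' @param fs optional sampling rate; when given, evaluate the digital
#'   design's response at `freq`.
#' @return gain values in `[0, 1]` (amplitude, single pass). For the
#'   high-pass response the `freq = 0` limit is 0.
#' @examples
#' butter_gain(filter_spec("lowpass", cutoff = 8), 8)  # 1/sqrt(2)
#' @export
butter_gain <- function(spec, freq, fs = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (any(!is.finite(freq)) || any(freq < 0))
    stop_field("freq", "must be finite and >= 0")
  if (!is.null(fs)) {
    ba <- butter_design(spec, fs)
    return(abs(freqz_mag(ba$b, ba$a, freq, fs)))
  }
  n <- spec$order
  if (spec$kind == "lowpass") {
    1 / sqrt(1 + (freq / spec$cutoff)^(2 * n))
  } else {
    g <- ifelse(freq == 0, 0, 1 / sqrt(1 + (spec$cutoff / pmax(freq, .Machine$double.xmin))^(2 * n)))
    g
  }
}

# digital design via the signal package (bilinear transform)
butter_design <- function(spec, fs) {
  if (spec$cutoff >= fs / 2)
    stop_field("cutoff", sprintf("must be below the Nyquist frequency %g Hz", fs / 2))
  bt <- signal::butter(spec$order, spec$cutoff / (fs / 2),
                       type = if (spec$kind == "lowpass") "low" else "high")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

# complex frequency response of a rational digital filter at freq (Hz)
freqz_mag <- function(b, a, freq, fs) {
  w <- 2 * pi * freq / fs
  vapply(w, function(wi) {
    zb <- exp(-1i * wi * (seq_along(b) - 1))
    za <- exp(-1i * wi * (seq_along(a) - 1))
    Mod(sum(b * zb) / sum(a * za))
  }, numeric(1))
}

# power response of the filter as applied (squared again when zero-phase)
filter_power_response <- function(spec, freq, fs) {
  ba <- butter_design(spec, fs)
  g <- freqz_mag(ba$b, ba$a, freq, fs)
  g^(if (spec$zero_phase) 4 else 2)
}

# forward-backward filtering with odd-reflection padding of
# 3 * max(length(b), length(a)) samples at each end; each pass starts
# from the steady state for its first sample, so edge transients from
# zero initial conditions are avoided
filtfilt_refl <- function(b, a, x) {
  npad <- 3L * max(length(b), length(a))
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  ext <- c(pre, x, post)
  dc <- sum(b) / sum(a)
  pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1L),
                              init.y = rep(z[1] * dc, length(a) - 1L)))
  }
  out <- rev(pass(rev(pass(ext))))
  out[(npad + 1):(npad + length(x))]
}

#' Apply a Butterworth filter to a channel
#'
#' Digital Butterworth filtering (bilinear design). With
#' `zero_phase = TRUE` (the default) the filter runs forward and backward
#' over the signal, giving zero phase lag and a squared magnitude
#' response; edges are handled by odd-reflection padding of
#' `3 * (order + 1)` samples. Output length equals input length and the
#' channel's history records the filter applied.
#'
#' @param ts an [eeg_channel()] (or numeric vector with `fs`).
#' @param spec a [filter_spec()].
#' @param fs sampling rate, required only for numeric input.
#' @return the filtered [eeg_channel()].
#' @examples
#' x <- noise_white(3000, fs = 200, seed = 1)
#' xl <- apply_filter(x, filter_spec("lowpass", cutoff = 8))
#' @export
apply_filter <- function(ts, spec, fs = NULL) {
  ts <- as_channel(ts, fs)
  stopifnot(inherits(spec, "filter_spec"))
  ba <- butter_design(spec, ts$fs)
  npad <- 3L * max(length(ba$b), length(ba$a))
  if (length(ts$samples) <= 3L * npad)
    stop(sprintf(
      "signal too short for stable order-%d filtering: %d samples, need > %d",
      spec$order, length(ts$samples), 3L * npad), call. = FALSE)
  y <- if (spec$zero_phase) {
    filtfilt_refl(ba$b, ba$a, ts$samples)
  } else {
    as.numeric(signal::filter(ba$b, ba$a, ts$samples))
  }
  out <- ts
  out$samples <- y
  out$history <- c(ts$history,
                   sprintf("%s(order=%d, cutoff=%g%s)", spec$kind, spec$order,
                           spec$cutoff, if (spec$zero_phase) ", zero-phase" else ""))
  attr(out, "filter") <- spec
  out
}
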