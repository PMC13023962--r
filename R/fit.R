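# Log-log transformation and weighted least-squares power-law fitting.

#' Log-log regression points from a spectrum
#'
#' Transforms the bins of a band to `x = log10(f)`, `y = log10(PSD)`.
#' When a per-bin uncertainty of the PSD is supplied, it is propagated to
#' the log scale to first order, `dy = sigma / (PSD * ln 10)`
#' (`sigma_mode = "linear"`), or taken as already being in log10 units
#' (`sigma_mode = "log10"`); fit weights are `w = 1/dy^2`.
#'
#' @param sp a `spectrum_estimate`.
#' @param bd a [band()], or `NULL` for the full range excluding DC.
#' @param sigma optional per-bin standard deviation of the PSD, aligned
#'   with `sp$freq` (full grid) or with the band's bins.
#' @param sigma_mode how to interpret `sigma`; see Details.
#' @return a data.frame with columns `freq`, `psd`, `x`, `y` and, when
#'   `sigma` is given, `dy` and `w`.
#' @export
to_loglog <- function(sp, bd = NULL, sigma = NULL,
                      sigma_mode = c("linear", "log10")) {
  stopifnot(inherits(sp, "spectrum_estimate"))
  sigma_mode <- match.arg(sigma_mode)
  full_sigma <- if (!is.null(sigma) && length(sigma) == length(sp$freq))
    sigma else NULL
  sl <- if (is.null(bd)) {
    out <- sp; k <- sp$freq > 0
    out$freq <- sp$freq[k]; out$psd <- sp$psd[k]; out
  } else band_slice(sp, bd)
  if (!is.null(sigma)) {
    if (!is.null(full_sigma))
      sigma <- full_sigma[match(sl$freq, sp$freq)]
    if (length(sigma) != length(sl$freq))
      stop_field("sigma", "length must match the full grid or the band's bins")
  }
  if (any(sl$psd <= 0))
    stop(sprintf("cannot log-transform: %d non-positive PSD bin(s) in band",
                 sum(sl$psd <= 0)), call. = FALSE)
  pts <- data.frame(freq = sl$freq, psd = sl$psd,
                    x = log10(sl$freq), y = log10(sl$psd))
  if (!is.null(sigma)) {
    dy <- if (sigma_mode == "linear") sigma / (sl$psd * log(10)) else sigma
    if (any(!is.finite(dy)) || any(dy <= 0))
      stop_field("sigma", "propagated uncertainties must be positive and finite")
    pts$dy <- dy
    pts$w <- 1 / dy^2
  }
  pts
}

# weighted simple linear regression via the stats machinery
wls_line <- function(x, y, w = NULL) {
  if (length(x) < 3L)
    stop("need at least 3 points for a power-law fit", call. = FALSE)
  if (!is.null(w) && (any(!is.finite(w)) || any(w <= 0)))
    stop("fit weights must be positive and finite", call. = FALSE)
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  sm <- quiet_perfect_fit(summary(fit))
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se_intercept = sm$coefficients[1, 2],
       se_slope = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       df = fit$df.residual,
       fitted = unname(stats::fitted(fit)))
}

new_specslope <- function(ls, pts, bd, settings, call) {
  structure(
    list(beta = -ls$slope, intercept = ls$intercept,
         se_beta = ls$se_slope, se_intercept = ls$se_intercept,
         r_squared = ls$r_squared, n_points = nrow(pts), df = ls$df,
         band = bd, points = pts, fitted = ls$fitted,
         settings = settings, call = call),
    class = "specslope")
}

#' Weighted least-squares line fit on log-log points
#'
#' Fits `y = intercept + slope * x` by (weighted) least squares and
#' returns it as a [specslope()] object with `beta = -slope`. This is the
#' estimation core used by all higher-level fitting entry points; it is
#' exact for collinear input.
#'
#' @param points a data.frame as returned by [to_loglog()] (columns `x`,
#'   `y`, optional `w`), or a numeric vector `x`.
#' @param y,w numeric vectors when `points` is given as `x`.
#' @return an object of class `specslope`.
#' @examples
#' f <- seq(1, 40, by = 0.5)
#' wls_fit(log10(f), 3 - 2 * log10(f))$beta  # exactly 2
#' @export
wls_fit <- function(points, y = NULL, w = NULL) {
  if (is.data.frame(points)) {
    x <- points$x; y <- points$y
    w <- points$w
    pts <- points
  } else {
    x <- points
    pts <- data.frame(x = x, y = y)
    if (!is.null(w)) pts$w <- w
  }
  ls <- wls_line(x, y, w)
  new_specslope(ls, pts, NULL, list(weighted = !is.null(w)), sys.call())
}

#' Estimate the scale-free (power-law) spectral exponent
#'
#' Fits `PSD(f) = c / f^beta` on log-log axes by (weighted) least
#' squares, the core estimator of this package. Methods exist for a raw
#' channel (filter, Welch PSD, then unit-weight fit), a precomputed
#' spectrum (optional per-bin uncertainties as weights), and a region
#' summary (mean spectrum weighted by the cross-channel standard
#' deviation). The exponent is stored signed (`beta` positive for a
#' decaying spectrum); printing reports its magnitude, the paper-standard
#' |beta| notation of the field.
#'
#' When a filter was applied, the band's PSD is divided by the filter's
#' exact power response before fitting (`compensate = TRUE`), removing
#' the roll-off bias near the cutoff; see the methods vignette.
#'
#' @param x an [eeg_channel()], `spectrum_estimate`, `region_summary`, or
#'   numeric vector (with `fs`).
#' @param ... passed between methods.
#' @return an object of class `specslope` with elements `beta`,
#'   `intercept` (log10 units), `se_beta`, `se_intercept`, `r_squared`,
#'   `n_points`, `band` and `points`, supporting `print()`, `summary()`,
#'   `coef()`, `confint()`, `predict()`, `residuals()`, `plot()` and
#'   `simulate()`.
#' @examples
#' x <- noise_powerlaw(6000, fs = 200, beta = 1.5, seed = 1)
#' fit <- specslope(x, band = band_low(), filter = filter_spec("lowpass"))
#' fit
#' coef(fit)
#' @export
specslope <- function(x, ...) UseMethod("specslope")

#' @rdname specslope
#' @param fs sampling rate for numeric input.
#' @export
specslope.default <- function(x, fs = NULL, ...) {
  specslope(as_channel(x, fs), ...)
}

#' @rdname specslope
#' @param band a [band()] to fit in, or `NULL` for the full range
#'   excluding DC.
#' @param filter optional [filter_spec()] applied before spectral
#'   estimation (low band pairs with a lowpass, high band with a
#'   highpass).
#' @param compensate divide the PSD by the applied filter's power
#'   response before fitting (default `TRUE`; ignored without `filter`).
#' @param nperseg,nfft,overlap,window,detrend Welch settings, see
#'   [welch_psd()].
#' @export
specslope.eeg_channel <- function(x, band = NULL, filter = NULL,
                                  compensate = TRUE, nperseg = 2048,
                                  nfft = nperseg, overlap = 0.5,
                                  window = "hamming",
                                  detrend = "constant", ...) {
  if (!is.null(filter)) x <- apply_filter(x, filter)
  sp <- welch_psd(x, nperseg = nperseg, nfft = nfft, overlap = overlap,
                  window = window, detrend = detrend)
  specslope(sp, band = band, filter = filter, compensate = compensate, ...)
}

#' @rdname specslope
#' @param sigma,sigma_mode per-bin PSD uncertainties, see [to_loglog()].
#' @export
specslope.spectrum_estimate <- function(x, band = NULL, sigma = NULL,
                                        sigma_mode = "linear",
                                        filter = NULL, compensate = TRUE,
                                        ...) {
  pts <- to_loglog(x, band, sigma = sigma, sigma_mode = sigma_mode)
  if (!is.null(filter) && compensate) {
    g <- filter_power_response(filter, pts$freq, x$fs)
    pts$psd <- pts$psd / g
    pts$y <- log10(pts$psd)
  }
  ls <- wls_line(pts$x, pts$y, pts$w)
  settings <- c(x$settings,
                list(weighted = !is.null(pts$w),
                     filter = if (!is.null(filter))
                       unclass(filter) else NULL,
                     compensated = !is.null(filter) && compensate),
                x$meta)
  new_specslope(ls, pts, band, settings, sys.call())
}

#' @export
print.specslope <- function(x, digits = 3, ...) {
  bd <- if (is.null(x$band)) "full range" else
    sprintf("%s band [%g, %g] Hz", x$band$name, x$band$f_lo, x$band$f_hi)
  cat(sprintf("<specslope> |beta| = %.*f (SE %.*f), %s, %d bins\n",
              digits, abs(x$beta), digits, x$se_beta, bd, x$n_points))
  cat(sprintf("  intercept = %.*f log10-units (SE %.*f), R² = %.4f%s\n",
              digits, x$intercept, digits, x$se_intercept, x$r_squared,
              if (isTRUE(x$settings$weighted)) ", weighted" else ""))
  invisible(x)
}

#' @export
summary.specslope <- function(object, ...) {
  structure(object, class = c("summary.specslope", "specslope"))
}

#' @export
print.summary.specslope <- function(x, ...) {
  print.specslope(x, digits = 4)
  ci <- confint.specslope(x)
  cat(sprintf("  95%% CI for |beta|: [%.4f, %.4f]\n", ci["beta", 1], ci["beta", 2]))
  if (isTRUE(x$settings$compensated))
    cat("  PSD compensated for the applied filter response\n")
  cat(sprintf("  residual range: [%.3g, %.3g] (log10 units)\n",
              min(x$points$y - x$fitted), max(x$points$y - x$fitted)))
  invisible(x)
}

#' @export
coef.specslope <- function(object, ...) {
  c(intercept = object$intercept, beta = object$beta)
}

#' @export
confint.specslope <- function(object, parm = c("beta", "intercept"),
                              level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  tq <- stats::qt(1 - (1 - level) / 2, df = object$df)
  est <- c(beta = abs(object$beta), intercept = object$intercept)
  se <- c(beta = object$se_beta, intercept = object$se_intercept)
  out <- cbind(est[parm] - tq * se[parm], est[parm] + tq * se[parm])
  colnames(out) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' @export
predict.specslope <- function(object, freq = NULL,
                              type = c("log10", "psd"), ...) {
  type <- match.arg(type)
  if (is.null(freq)) freq <- object$points$freq
  if (any(freq <= 0)) stop_field("freq", "must be > 0")
  yhat <- object$intercept - object$beta * log10(freq)
  if (type == "psd") 10^yhat else yhat
}

#' @export
residuals.specslope <- function(object, ...) {
  object$points$y - object$fitted
}

#' @export
plot.specslope <- function(x, ...) {
  graphics::plot(x$points$x, x$points$y, pch = 16, cex = 0.5,
                 xlab = "log10 frequency (Hz)", ylab = "log10 PSD", ...)
  graphics::abline(x$intercept, -x$beta, col = "red", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("|beta| = %.3f", abs(x$beta)))
  invisible(x)
}

#' @export
simulate.specslope <- function(object, nsim = 1, seed = NULL,
                               n_samples = 12000, fs = 200, ...) {
  lapply(seq_len(nsim), function(i) {
    noise_powerlaw(n_samples, fs, beta = abs(object$beta),
                   seed = if (is.null(seed)) NULL else sub_seed(seed, i))
  })
}

#' Min-max normalization of region exponents
#'
#' Maps each region's exponent to
#' `(beta_i - beta_min) / (beta_max - beta_min)`, the ratio used to color
#' regions on brain projections: the smallest-exponent region maps to 0,
#' the largest to 1.
#'
#' @param betas named numeric vector of region exponents (>= 2 regions,
#'   not all equal).
#' @return named numeric vector of class `delta_beta` in `[0, 1]`, with
#'   attributes `beta_min` and `beta_max`.
#' @examples
#' delta_beta(c(A = 1, B = 2, C = 3))
#' @export
delta_beta <- function(betas) {
  if (!is.numeric(betas) || length(betas) < 2L)
    stop_field("betas", "need exponents for at least 2 regions")
  if (anyNA(betas) || any(!is.finite(betas)))
    stop_field("betas", "must be finite")
  rng <- range(betas)
  if (rng[1] == rng[2])
    stop("degenerate range: all region exponents are equal", call. = FALSE)
  structure((betas - rng[1]) / (rng[2] - rng[1]),
            beta_min = rng[1], beta_max = rng[2], class = "delta_beta")
}

#' @export
print.delta_beta <- function(x, ...) {
  cat(sprintf("<delta_beta> min-max normalized exponents (beta in [%g, %g])\n",
              attr(x, "beta_min"), attr(x, "beta_max")))
  print(round(unclass(x), 4))
  invisible(x)
}
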