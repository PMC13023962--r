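# Region-level aggregation of channel spectra.

#' Aggregate channel spectra into a region summary
#'
#' Per-bin arithmetic mean and standard deviation of the PSD pooled over
#' all channels of all subjects in a region. Pooling across the whole
#' region (rather than averaging within subjects first) is the
#' conservative choice: between-subject exponent variability exceeds the
#' within-subject one, so the pooled SD is the larger, more honest
#' uncertainty for the weighted region fit.
#'
#' @param spectra list of `spectrum_estimate` objects on identical
#'   frequency grids (typically all channels of one region).
#' @param region optional region label; taken from the first spectrum's
#'   metadata when missing.
#' @return an object of class `region_summary`: list with `region`,
#'   `freq`, `mean_psd`, `sd_psd` (population SD, 0 for a single
#'   spectrum), `n_channels`, `n_subjects`, `fs`, `settings`.
#' @seealso [specslope()] for the weighted fit on the summary.
#' @export
aggregate_region <- function(spectra, region = NULL) {
  if (!is.list(spectra) || length(spectra) == 0L)
    stop_field("spectra", "must be a non-empty list of spectra")
  if (inherits(spectra, "spectrum_estimate")) spectra <- list(spectra)
  ok <- vapply(spectra, inherits, logical(1), "spectrum_estimate")
  if (!all(ok)) stop_field("spectra", "all elements must be spectrum_estimate")
  f0 <- spectra[[1]]$freq
  same <- vapply(spectra, function(s)
    length(s$freq) == length(f0) && all(s$freq == f0), logical(1))
  if (!all(same))
    stop(sprintf("mismatched frequency grids in %d of %d spectra",
                 sum(!same), length(spectra)), call. = FALSE)
  p <- vapply(spectra, `[[`, numeric(length(f0)), "psd")
  p <- matrix(p, nrow = length(f0))
  m <- rowMeans(p)
  # population SD (divisor n): a single spectrum has SD 0 by definition
  s <- sqrt(pmax(rowMeans(p^2) - m^2, 0))
  subjects <- unique(stats::na.omit(vapply(
    spectra, function(x) x$meta$subject_id %||% NA_character_, character(1))))
  structure(
    list(region = region %||% spectra[[1]]$meta$region, freq = f0,
         mean_psd = m, sd_psd = s, n_channels = length(spectra),
         n_subjects = max(length(subjects), 1L), fs = spectra[[1]]$fs,
         settings = spectra[[1]]$settings),
    class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("<region_summary> %s: %d channel(s), %d subject(s), %d bins\n",
              x$region %||% "?", x$n_channels, x$n_subjects, length(x$freq)))
  invisible(x)
}

# view of a region summary's mean spectrum as a spectrum_estimate
mean_spectrum <- function(rs) {
  structure(
    list(freq = rs$freq, psd = rs$mean_psd, fs = rs$fs,
         settings = rs$settings,
         meta = list(subject_id = NA_character_, region = rs$region,
                     channel_id = NA_character_, history = "region mean")),
    class = "spectrum_estimate")
}

#' @rdname specslope
#' @param weighting for a region summary: `"linear"` propagates the
#'   cross-channel SD of the linear-domain PSD into log space
#'   (`dy = sd / (psd * ln 10)`, the default), `"none"` fits unweighted.
#' @export
specslope.region_summary <- function(x, band = NULL, filter = NULL,
                                     compensate = TRUE,
                                     weighting = c("linear", "none"), ...) {
  weighting <- match.arg(weighting)
  sp <- mean_spectrum(x)
  sigma <- if (weighting == "linear") x$sd_psd else NULL
  if (!is.null(sigma) && any(sigma <= 0)) {
    warning("zero cross-channel SD in some bins; falling back to an unweighted fit",
            call. = FALSE)
    sigma <- NULL
  }
  fit <- specslope(sp, band = band, sigma = sigma, sigma_mode = "linear",
                   filter = filter, compensate = compensate, ...)
  fit$settings$region <- x$region
  fit$settings$n_channels <- x$n_channels
  fit$settings$n_subjects <- x$n_subjects
  fit
}
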