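#' Single-channel electrophysiological time series
#'
#' Container for one uniformly sampled channel together with its sampling
#' rate and recording metadata (subject, region, channel, age, sex). All
#' simulators and the real-data readers return this class; filtering and
#' spectral estimation accept it.
#'
#' @param samples numeric vector of signal values (arbitrary units, e.g.
#'   microvolts); must be finite and of length at least 2.
#' @param fs sampling rate in Hz (positive).
#' @param subject_id,region,channel_id optional character identifiers.
#' @param age optional age in years.
#' @param sex optional sex label.
#' @param history character vector of processing steps already applied.
#' @return an object of class `eeg_channel`: a list with elements
#'   `samples`, `fs`, `subject_id`, `region`, `channel_id`, `age`, `sex`
#'   and `history`.
#' @examples
#' ch <- eeg_channel(sin(2 * pi * 5 * (0:999) / 200), fs = 200)
#' ch
#' @export
eeg_channel <- function(samples, fs, subject_id = NA_character_,
                        region = NA_character_, channel_id = NA_character_,
                        age = NA_real_, sex = NA_character_,
                        history = character()) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop_field("samples", "must be a numeric vector of length >= 2")
  if (anyNA(samples) || !all(is.finite(samples)))
    stop_field("samples", "must contain only finite values")
  check_scalar(fs, "fs")
  if (fs <= 0) stop_field("fs", "must be > 0")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         subject_id = subject_id, region = region, channel_id = channel_id,
         age = age, sex = sex, history = history),
    class = "eeg_channel")
}

#' @export
print.eeg_channel <- function(x, ...) {
  cat(sprintf("<eeg_channel> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  meta <- c(subject = x$subject_id, region = x$region, channel = x$channel_id)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = ": ", collapse = ", "), "\n")
  if (length(x$history))
    cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
length.eeg_channel <- function(x) length(x$samples)

# coerce numeric input to a channel when fs is supplied alongside
as_channel <- function(x, fs = NULL) {
  if (inherits(x, "eeg_channel")) return(x)
  if (is.numeric(x)) {
    if (is.null(fs)) stop("numeric input requires 'fs'", call. = FALSE)
    return(eeg_channel(x, fs))
  }
  stop("expected an 'eeg_channel' or a numeric vector", call. = FALSE)
}
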