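# Cohort input/output: delimited-text serialization and a minimal EDF
# (European Data Format) reader/writer for continuous recordings.

#' Write a cohort to a directory of text files
#'
#' Serializes each channel to a one-column text file (samples at 10
#' significant digits) plus a `metadata.csv` table with columns
#' `subject_id`, `region`, `channel`, `fs`, `age`, `sex`,
#' `true_beta_low`, `true_beta_high`, `file`. [read_channel_table()] on
#' the metadata file restores the cohort.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if missing).
#' @return the metadata CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- cohort$truth
  files <- character(length(cohort$channels))
  for (i in seq_along(cohort$channels)) {
    ch <- cohort$channels[[i]]
    files[i] <- paste0(ch$channel_id, ".txt")
    writeLines(sprintf("%.10g", ch$samples), file.path(dir, files[i]))
  }
  meta <- data.frame(
    subject_id = tr$subject_id, region = tr$region, channel = tr$channel_id,
    fs = vapply(cohort$channels, `[[`, numeric(1), "fs"),
    age = tr$age, sex = tr$sex,
    true_beta_low = tr$beta_low, true_beta_high = tr$beta_high,
    file = files)
  path <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a channel metadata table
#'
#' Loads a cohort described by a metadata CSV with required columns
#' `subject_id`, `region`, `channel`, `fs` and `file` (per-channel signal
#' paths, relative to the metadata file; one-column delimited text or
#' EDF by file extension). Optional columns `age`, `sex`,
#' `true_beta_low`, `true_beta_high` are carried along. Channels with
#' non-finite samples are rejected with a per-channel report, and all
#' channels must share one sampling rate.
#'
#' @param path path to the metadata CSV.
#' @return an `eeg_cohort`.
#' @export
read_channel_table <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "region", "channel", "fs", "file")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop(sprintf("metadata is missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (length(unique(meta$fs)) != 1L)
    stop(sprintf("sampling-rate mismatch across channels: fs in {%s}",
                 paste(sort(unique(meta$fs)), collapse = ", ")), call. = FALSE)
  base <- dirname(path)
  bad <- character()
  channels <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    f <- file.path(base, meta$file[i])
    if (!file.exists(f)) { bad <- c(bad, sprintf("%s: file not found", meta$channel[i])); next }
    x <- if (grepl("\\.edf$", f, ignore.case = TRUE)) {
      read_edf(f)[[1]]$samples
    } else {
      as.numeric(readLines(f))
    }
    if (anyNA(x) || !all(is.finite(x))) {
      bad <- c(bad, sprintf("%s: %d non-finite sample(s)", meta$channel[i],
                            sum(!is.finite(x))))
      next
    }
    channels[[i]] <- eeg_channel(
      x, meta$fs[i], subject_id = meta$subject_id[i], region = meta$region[i],
      channel_id = meta$channel[i],
      age = if ("age" %in% names(meta)) meta$age[i] else NA_real_,
      sex = if ("sex" %in% names(meta)) meta$sex[i] else NA_character_)
  }
  if (length(bad))
    stop(paste0("rejected channel(s):\n  ", paste(bad, collapse = "\n  ")),
         call. = FALSE)
  truth <- data.frame(
    subject_id = meta$subject_id, region = meta$region,
    channel_id = meta$channel,
    beta_low = if ("true_beta_low" %in% names(meta)) meta$true_beta_low else NA_real_,
    beta_high = if ("true_beta_high" %in% names(meta)) meta$true_beta_high else NA_real_,
    age = if ("age" %in% names(meta)) meta$age else NA_real_,
    sex = if ("sex" %in% names(meta)) meta$sex else NA_character_)
  regions <- unique(truth$region)
  structure(
    list(channels = channels, truth = truth,
         spec = list(regions = data.frame(region = regions),
                     n_subjects = max(table(unique(truth[c("region", "subject_id")])$region)),
                     n_channels = max(table(truth$subject_id)),
                     between_sd = NA_real_, within_sd = NA_real_,
                     duration_s = length(channels[[1]]$samples) / meta$fs[1],
                     fs = meta$fs[1], peak = NULL, seed = NA)),
    class = "eeg_cohort")
}

pad_field <- function(x, width) {
  s <- substr(format(x, width = width), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write channels to an EDF file
#'
#' Minimal EDF (European Data Format) writer for continuous recordings:
#' all channels must share sampling rate and length, and the length must
#' be a whole number of `record_s`-second records. Samples are stored as
#' 16-bit integers scaled between each channel's physical minimum and
#' maximum, so round-tripping is exact to the digitization resolution
#' (range / 65535) plus the 8-character header precision of the physical
#' range.
#'
#' @param channels an [eeg_channel()] or list of them.
#' @param path output path.
#' @param record_s data-record duration in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(channels, path, record_s = 1) {
  if (inherits(channels, "eeg_channel")) channels <- list(channels)
  if (!is.list(channels) ||
      !all(vapply(channels, inherits, logical(1), "eeg_channel")))
    stop_field("channels", "must be an eeg_channel or a list of them")
  fs <- unique(vapply(channels, `[[`, numeric(1), "fs"))
  ns <- unique(vapply(channels, length, integer(1)))
  if (length(fs) != 1L || length(ns) != 1L)
    stop("all channels must share sampling rate and length", call. = FALSE)
  spr <- fs * record_s
  if (spr != round(spr) || ns %% spr != 0)
    stop(sprintf("signal length %d is not a whole number of %g-s records at %g Hz",
                 ns, record_s, fs), call. = FALSE)
  nrec <- ns %/% spr
  nsig <- length(channels)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X", 80), pad_field("synthetic", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + nsig), 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field(format(record_s), 8), pad_field(nsig, 4))
  writeChar(hdr, con, eos = NULL)
  pmin <- pmax <- numeric(nsig)
  for (i in seq_len(nsig)) {
    r <- range(channels[[i]]$samples)
    if (r[1] == r[2]) r[2] <- r[1] + 1
    pmin[i] <- as.numeric(formatC(r[1], format = "g", digits = 6))
    pmax[i] <- as.numeric(formatC(r[2], format = "g", digits = 6))
    if (pmin[i] > r[1]) pmin[i] <- r[1] - abs(r[1]) * 1e-5 - 1e-12
    if (pmax[i] < r[2]) pmax[i] <- r[2] + abs(r[2]) * 1e-5 + 1e-12
  }
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, pad_field, character(1), width), collapse = ""),
              con, eos = NULL)
  field(vapply(seq_len(nsig), function(i)
    channels[[i]]$channel_id %||% sprintf("ch%d", i), character(1)), 16)
  field(rep("", nsig), 80)                      # transducer
  field(rep("uV", nsig), 8)                     # physical dimension
  field(formatC(pmin, format = "g", digits = 6), 8)
  field(formatC(pmax, format = "g", digits = 6), 8)
  field(rep("-32768", nsig), 8)
  field(rep("32767", nsig), 8)
  field(rep("", nsig), 80)                      # prefiltering
  field(rep(format(spr), nsig), 8)
  field(rep("", nsig), 32)
  dig <- lapply(seq_len(nsig), function(i) {
    x <- channels[[i]]$samples
    as.integer(round((x - pmin[i]) / (pmax[i] - pmin[i]) * 65535 - 32768))
  })
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(nsig))
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Minimal reader for continuous EDF recordings as produced by
#' [write_edf()] and by standard acquisition systems (16-bit integer
#' samples, uniform records).
#'
#' @param path EDF file path.
#' @return a list of [eeg_channel()] objects, one per signal.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8)                                         # version
  rd(80); rd(80); rd(8); rd(8)                  # patient/recording/date/time
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  nsig <- as.integer(rd(4))
  if (is.na(nsig) || nsig < 1) stop("malformed EDF header", call. = FALSE)
  labels <- vapply(seq_len(nsig), function(i) rd(16), character(1))
  for (i in seq_len(nsig)) rd(80)
  for (i in seq_len(nsig)) rd(8)
  pmin <- vapply(seq_len(nsig), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(nsig), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nsig), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nsig), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nsig)) rd(80)
  spr <- vapply(seq_len(nsig), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nsig)) rd(32)
  out <- lapply(seq_len(nsig), function(i) numeric(nrec * spr[i]))
  for (r in seq_len(nrec)) {
    for (i in seq_len(nsig)) {
      d <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      phys <- pmin[i] + (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
      out[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  lapply(seq_len(nsig), function(i)
    eeg_channel(out[[i]], fs = spr[i] / record_s, channel_id = labels[i],
                history = "read_edf"))
}
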