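# Minimal EDF (European Data Format, 16-bit) writer/reader, sufficient for
# continuous multichannel recordings with a common sampling rate. One data
# record per second; the recording is zero-padded to a whole number of
# records (the events table carries the true timing, so trailing padding is
# inert). Physical range ±3276.7 µV against digital ±32767 gives a 0.1 µV
# quantization step.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a continuous recording to an EDF file
#'
#' @param eeg `"continuous_eeg"` object (µV).
#' @param path output file path.
#' @param phys_range symmetric physical range in µV (default 3276.7,
#'   i.e. 0.1 µV per 16-bit step). Samples outside the range are clipped.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path, phys_range = 3276.7) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  ns <- nrow(eeg$data)
  fs <- eeg$srate
  n_rec <- ceiling(ncol(eeg$data) / fs)
  dat <- matrix(0, ns, n_rec * fs)
  dat[, seq_len(ncol(eeg$data))] <- eeg$data
  dig <- round(pmin(pmax(dat / phys_range, -1), 1) * 32767)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    edf_pad("0", 8L),
    edf_pad(paste0("X X X ", if (length(eeg$meta$subject)) eeg$meta$subject else "X"), 80L),
    edf_pad("Startdate X X X X", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + ns), 8L), edf_pad("", 44L),
    edf_pad(n_rec, 8L), edf_pad("1", 8L), edf_pad(ns, 4L))
  writeChar(paste(hdr, collapse = ""), con, eos = NULL)
  sig_hdr <- paste0(
    paste(edf_pad(eeg$channels, 16L), collapse = ""),
    paste(rep(edf_pad("AgAgCl electrode", 80L), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8L), ns), collapse = ""),
    paste(rep(edf_pad(-phys_range, 8L), ns), collapse = ""),
    paste(rep(edf_pad(phys_range, 8L), ns), collapse = ""),
    paste(rep(edf_pad(-32767L, 8L), ns), collapse = ""),
    paste(rep(edf_pad(32767L, 8L), ns), collapse = ""),
    paste(rep(edf_pad("", 80L), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8L), ns), collapse = ""),
    paste(rep(edf_pad("", 32L), ns), collapse = ""))
  writeChar(sig_hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1L) * fs + 1L):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports the subset of EDF this package writes: a common sampling rate
#' across signals and one-second data records.
#'
#' @param path EDF file path.
#' @return `"continuous_eeg"` object (µV; includes any trailing
#'   zero-padding added to fill the last data record).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nbytes) trimws(readChar(con, nbytes, useBytes = TRUE))
  rd(8L)                        # version
  patient <- rd(80L)
  rd(80L); rd(8L); rd(8L)
  readChar(con, 8L)             # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16L),
                          character(1)))
  rd(80L * ns); rd(8L * ns)
  pmin_v <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  pmax_v <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dmin_v <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dmax_v <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  rd(80L * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  rd(32L * ns)
  if (length(unique(spr)) != 1L) stop("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  dat <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2L,
                   endian = "little")
    dat[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
      matrix(raw, ns, spr[1], byrow = TRUE)
  }
  gain <- (pmax_v - pmin_v) / (dmax_v - dmin_v)
  off <- pmax_v - gain * dmax_v
  dat <- dat * gain + off
  subject <- sub("^X X X ", "", patient)
  continuous_eeg(dat, labels, srate = fs,
                 meta = list(subject = if (subject == "X") NULL else subject))
}

#' Write a synthetic cohort to disk
#'
#' One EDF recording and one events TSV per subject, plus a JSON cohort
#' manifest recording the full generator parameters and seed. The layout
#' round-trips through [read_edf()] and [read_events_tsv()] up to the
#' 16-bit EDF quantization (0.1 µV).
#'
#' @param bundles list of `"recording_bundle"` objects (from
#'   [generate_cohort()]).
#' @param dir output directory (created if needed).
#' @param params optional `"cohort_params"` stored in the manifest.
#' @return tibble manifest of written files, invisibly.
#' @export
write_dataset <- function(bundles, dir, params = NULL) {
  if (length(bundles) == 0L) stop("empty cohort: nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(bundles, function(b) {
    stopifnot(inherits(b, "recording_bundle"))
    edf <- file.path(dir, paste0(b$subject, ".edf"))
    tsv <- file.path(dir, paste0(b$subject, "_events.tsv"))
    write_edf(b$eeg, edf)
    write.table(b$events, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    tibble::tibble(subject = b$subject, group = b$group, edf = basename(edf),
                   events = basename(tsv))
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(
    list(subjects = manifest,
         params = if (!is.null(params)) unclass_params(params) else NULL),
    file.path(dir, "cohort_manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(manifest)
}

unclass_params <- function(p) {
  p <- unclass(p)
  lapply(p, function(x) if (inherits(x, "group_params")) unclass(x) else x)
}

#' Read an events TSV
#'
#' @param path events TSV path (the [write_dataset()] schema).
#' @return events tibble with `correct` as integer and `rt_ms` numeric.
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  tibble::as_tibble(ev)
}
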