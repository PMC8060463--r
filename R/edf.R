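# Minimal EDF (European Data Format) reading and writing.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of 16-bit little-endian integers; physical values are recovered
# by linear scaling between the digital and physical ranges declared per
# signal.  This implementation covers continuous, equal-rate multichannel
# recordings — the layout used by scalp-EEG archives such as CHB-MIT — and
# writes one-second data records.

fmt_ascii <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) {
    stop_sdcae(sprintf("EDF field '%s' exceeds %d characters", s, width),
               "sdcae_format_error")
  }
  formatC(s, width = width, flag = "-")
}

fmt_num8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(signif(x, digits), format = "g", digits = digits)
    if (nchar(s) <= 8) return(formatC(s, width = 8, flag = "-"))
  }
  stop_sdcae(sprintf("cannot format %g in 8 characters", x),
             "sdcae_format_error")
}

#' Write a recording to an EDF file
#'
#' Encodes the signal as 16-bit integers with per-channel physical scaling
#' over symmetric ranges, in one-second data records.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  n <- nrow(rec$signal)
  nc <- ncol(rec$signal)
  if (n %% fs != 0) {
    stop_sdcae("recording length must be a whole number of seconds",
               "sdcae_format_error")
  }
  n_rec <- n %/% fs
  dmin <- -32768; dmax <- 32767
  pmax <- pmax(apply(abs(rec$signal), 2, max), 1)
  pmax <- signif(pmax * 1.0001, 6)  # keep extremes strictly inside range
  pmin <- -pmax
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fmt_ascii("0", 8),
    fmt_ascii(rec$subject_id, 80),
    fmt_ascii(paste("Startdate 01-JAN-2020", rec$source_file), 80),
    fmt_ascii("01.01.20", 8),
    fmt_ascii("00.00.00", 8),
    fmt_ascii(256 * (nc + 1), 8),
    fmt_ascii("", 44),
    fmt_ascii(n_rec, 8),
    fmt_ascii(1, 8),
    fmt_ascii(nc, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, fmt_ascii, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$channel_names, 16)
  field(rep("", nc), 80)                      # transducer
  field(rep("uV", nc), 8)
  writeChar(paste0(vapply(pmin, fmt_num8, ""), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmax, fmt_num8, ""), collapse = ""), con, eos = NULL)
  field(rep(dmin, nc), 8)
  field(rep(dmax, nc), 8)
  field(rep("", nc), 80)                      # prefiltering
  field(rep(fs, nc), 8)                       # samples per data record
  field(rep("", nc), 32)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    block <- rec$signal[rows, , drop = FALSE]
    dig <- round(sweep(sweep(block, 2, pmin, "-"), 2, gain, "/")) + dmin
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_ascii <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < n) {
    stop_sdcae("EDF file truncated in header", "sdcae_parse_error")
  }
  trimws(raw)
}

#' Read an EDF file
#'
#' Parses the header and data records and returns physically scaled values.
#' All signals must share one sampling rate.
#'
#' @param path Path to an EDF file.
#' @param expected_sample_rate_hz If non-`NULL`, reading a file with a
#'   different sampling rate raises a format error (the pipeline assumes a
#'   homogeneous 256 Hz dataset).
#' @return An `eeg_recording`; channel labels are preserved verbatim.
#' @export
read_edf <- function(path, expected_sample_rate_hz = NULL) {
  if (!file.exists(path)) {
    stop_sdcae(paste0("file not found: ", path), "sdcae_parse_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                           # version
  patient <- read_ascii(con, 80)
  read_ascii(con, 80); read_ascii(con, 8); read_ascii(con, 8)
  hdr_bytes <- suppressWarnings(as.integer(read_ascii(con, 8)))
  read_ascii(con, 44)
  n_rec <- suppressWarnings(as.integer(read_ascii(con, 8)))
  rec_dur <- suppressWarnings(as.numeric(read_ascii(con, 8)))
  nc <- suppressWarnings(as.integer(read_ascii(con, 4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, nc)) || nc < 1 || n_rec < 0) {
    stop_sdcae("malformed EDF header", "sdcae_parse_error")
  }
  rd_fields <- function(width) {
    vapply(seq_len(nc), function(i) read_ascii(con, width), "")
  }
  labels <- rd_fields(16)
  rd_fields(80)
  rd_fields(8)
  pmin <- as.numeric(rd_fields(8))
  pmax <- as.numeric(rd_fields(8))
  dmin <- as.numeric(rd_fields(8))
  dmax <- as.numeric(rd_fields(8))
  rd_fields(80)
  spr <- suppressWarnings(as.integer(rd_fields(8)))
  rd_fields(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr))) {
    stop_sdcae("malformed EDF signal headers", "sdcae_parse_error")
  }
  if (length(unique(spr)) != 1L || rec_dur <= 0) {
    stop_sdcae("channels disagree on samples per record", "sdcae_format_error")
  }
  fs <- spr[1] / rec_dur
  if (!is.null(expected_sample_rate_hz) &&
      !isTRUE(all.equal(fs, expected_sample_rate_hz))) {
    stop_sdcae(sprintf("sampling rate %g Hz, expected %g Hz", fs,
                       expected_sample_rate_hz), "sdcae_format_error")
  }
  n_per_rec <- sum(spr)
  payload <- readBin(con, integer(), n = n_rec * n_per_rec, size = 2,
                     signed = TRUE, endian = "little")
  if (length(payload) < n_rec * n_per_rec) {
    stop_sdcae("EDF file truncated: fewer samples than declared",
               "sdcae_parse_error")
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  sig <- matrix(0, n_rec * spr[1], nc)
  payload <- array(payload, c(spr[1], nc, n_rec))
  for (ch in seq_len(nc)) {
    sig[, ch] <- as.vector(payload[, ch, ]) * gain[ch] +
      (pmin[ch] - dmin[ch] * gain[ch])
  }
  subject <- if (nzchar(patient)) strsplit(patient, "\\s+")[[1]][1] else
    sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  structure(list(subject_id = subject, signal = sig, sample_rate_hz = fs,
                 channel_names = labels, source_file = basename(path)),
            class = "eeg_recording")
}
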