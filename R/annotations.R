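# Seizure annotations: the CHB-MIT summary text dialect, interval
# filtering, and channel canonicalization.

#' The canonical CHB-MIT bipolar montage
#'
#' The 23 longitudinal-bipolar channel labels used by the CHB-MIT scalp EEG
#' recordings (10-20 electrode names, modified combinatorial nomenclature).
#' The archive genuinely repeats the label `T8-P8`; the duplicate is kept so
#' positional matching against real files works unchanged.
#'
#' @return Character vector of 23 labels.
#' @export
chbmit_channels <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ", "P7-T7", "T7-FT9",
    "FT9-FT10", "FT10-T8", "T8-P8")
}

#' Create an annotation set
#'
#' @param subject_id Subject label.
#' @param intervals Data frame with columns `file`, `start_s`, `end_s`.
#' @return An `annotation_set` with intervals sorted by file and start;
#'   overlapping intervals within a file are rejected.
#' @export
annotation_set <- function(subject_id, intervals) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) > 0) {
    if (any(intervals$end_s <= intervals$start_s)) {
      stop_sdcae("annotation intervals must have end_s > start_s",
                 "sdcae_validation_error")
    }
    intervals <- intervals[order(intervals$file, intervals$start_s), ,
                           drop = FALSE]
    rownames(intervals) <- NULL
    for (f in unique(intervals$file)) {
      iv <- intervals[intervals$file == f, ]
      if (nrow(iv) > 1 && any(iv$start_s[-1] < iv$end_s[-nrow(iv)])) {
        stop_sdcae(paste0("overlapping seizure intervals in ", f),
                   "sdcae_validation_error")
      }
    }
  }
  structure(list(subject_id = subject_id, intervals = intervals),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d seizure interval(s), %g s total\n",
              x$subject_id, nrow(x$intervals),
              sum(x$intervals$end_s - x$intervals$start_s)))
  invisible(x)
}

#' Parse a CHB-MIT-style summary annotation file
#'
#' Reads the plain-text dialect in which each recording appears as a block
#' `File Name: <name>.edf`, `Number of Seizures in File: n`, followed by
#' `n` pairs `Seizure [k ]Start Time: s seconds` / `Seizure [k ]End Time: e
#' seconds`.
#'
#' @param path Path to the summary text file.
#' @param subject_id Optional subject label; defaults to the prefix of the
#'   first file name.
#' @return An `annotation_set` with one interval per start/end pair.
#' @export
parse_summary <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    stop_sdcae(paste0("file not found: ", path), "sdcae_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  file_idx <- grep("^\\s*File Name\\s*:", lines)
  rows <- list()
  for (i in seq_along(file_idx)) {
    from <- file_idx[i]
    to <- if (i < length(file_idx)) file_idx[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    fname <- trimws(sub("^\\s*File Name\\s*:", "", block[1]))
    nline <- grep("^\\s*Number of Seizures in File\\s*:", block, value = TRUE)
    if (length(nline) != 1) {
      stop_sdcae(paste0("block for ", fname,
                        " lacks a seizure count line"), "sdcae_parse_error")
    }
    n_seiz <- suppressWarnings(as.integer(sub(".*:", "", nline)))
    if (is.na(n_seiz) || n_seiz < 0) {
      stop_sdcae(paste0("unreadable seizure count for ", fname),
                 "sdcae_parse_error")
    }
    starts <- grep("^\\s*Seizure( \\d+)? Start Time\\s*:", block, value = TRUE)
    ends <- grep("^\\s*Seizure( \\d+)? End Time\\s*:", block, value = TRUE)
    if (length(starts) != n_seiz || length(ends) != n_seiz) {
      stop_sdcae(sprintf(
        "%s declares %d seizure(s) but lists %d start / %d end time(s)",
        fname, n_seiz, length(starts), length(ends)), "sdcae_parse_error")
    }
    num <- function(x) as.numeric(sub(".*:\\s*([-0-9.]+).*", "\\1", x))
    if (n_seiz > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        file = fname, start_s = num(starts), end_s = num(ends))
    }
  }
  intervals <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), start_s = numeric(), end_s = numeric())
  if (is.null(subject_id)) {
    subject_id <- if (length(file_idx)) {
      sub("_.*$", "", trimws(sub("^\\s*File Name\\s*:", "",
                                 lines[file_idx[1]])))
    } else {
      sub("-summary.*$", "", basename(path))
    }
  }
  annotation_set(subject_id, intervals)
}

#' Write annotations in the CHB-MIT summary dialect
#'
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @param sample_rate_hz Rate recorded in the file header line.
#' @param files Optional character vector of file names to emit blocks for
#'   (files without seizures get a zero-count block); defaults to the files
#'   present in `ann`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(ann, path, sample_rate_hz = 256, files = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  files <- files %||% unique(ann$intervals$file)
  out <- c(sprintf("Data Sampling Rate: %g Hz", sample_rate_hz), "")
  for (f in files) {
    iv <- ann$intervals[ann$intervals$file == f, , drop = FALSE]
    out <- c(out,
             paste0("File Name: ", f),
             "File Start Time: 00:00:00",
             sprintf("File End Time: %s", "01:00:00"),
             sprintf("Number of Seizures in File: %d", nrow(iv)))
    for (r in seq_len(nrow(iv))) {
      out <- c(out,
               sprintf("Seizure %d Start Time: %g seconds", r, iv$start_s[r]),
               sprintf("Seizure %d End Time: %g seconds", r, iv$end_s[r]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Drop seizures shorter than a minimum duration
#'
#' Short events (under 10 s by default) are excluded from the study design;
#' intervals with `end_s - start_s >= min_duration_s` are retained.
#'
#' @param ann An `annotation_set`.
#' @param min_duration_s Minimum seizure duration in seconds.
#' @return A filtered `annotation_set`.
#' @export
filter_seizures <- function(ann, min_duration_s = 10) {
  stopifnot(inherits(ann, "annotation_set"))
  keep <- (ann$intervals$end_s - ann$intervals$start_s) >= min_duration_s
  annotation_set(ann$subject_id, ann$intervals[keep, , drop = FALSE])
}

normalize_label <- function(x) {
  toupper(gsub("\\s+", "", x))
}

#' Reorder channels to a canonical montage
#'
#' Re-orders (and subsets) the recording's columns so that column `j`
#' carries the channel named `canonical_list[j]`.  Label matching is
#' case-insensitive and whitespace-stripped; when a label occurs more than
#' once in the recording the first occurrence is used.
#'
#' @param rec An `eeg_recording`.
#' @param canonical_list Ordered channel names (defaults to the 23 CHB-MIT
#'   bipolar labels).
#' @return The recording with 23 canonically ordered channels; extra
#'   channels are dropped.
#' @export
canonicalize_channels <- function(rec, canonical_list = chbmit_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  have <- normalize_label(rec$channel_names)
  want <- normalize_label(canonical_list)
  pos <- match(want, have)  # first occurrence wins
  if (anyNA(pos)) {
    stop_sdcae(paste0("recording is missing canonical channel(s): ",
                      paste(canonical_list[is.na(pos)], collapse = ", ")),
               "sdcae_channel_error")
  }
  rec$signal <- rec$signal[, pos, drop = FALSE]
  rec$channel_names <- canonical_list
  rec
}
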