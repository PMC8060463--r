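# Synthetic multichannel EEG with annotated seizures.
#
# Background activity is Gaussian noise spectrally shaped toward 1/f, which
# looks and scales like resting scalp EEG.  Ictal activity superimposes a
# rhythmic ~3 Hz spike-and-wave-like waveform (fundamental plus decaying
# harmonics, random per-channel phase) on a subset of channels.  The
# generator is deliberately simple: it is a test harness for the pipeline,
# not a physiological simulator.

#' Specification of a synthetic EEG recording
#'
#' @param duration_s Recording length in seconds (positive; integral values
#'   recommended so the recording fills whole EDF data records).
#' @param n_channels Number of channels (23 mirrors the CHB-MIT montage).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param background_amp_uv RMS amplitude of the background noise, microvolts.
#' @param ictal_amp_uv Amplitude of the ictal rhythmic component,
#'   microvolts; must exceed `background_amp_uv` so the classes are
#'   separable.
#' @param ictal_freq_hz Fundamental frequency of the ictal rhythm.
#' @param channel_involvement Fraction of channels carrying the ictal
#'   rhythm, in (0, 1].
#' @param seed Integer seed; equal seeds give bit-identical recordings.
#' @return List of class `signal_spec`.
#' @export
signal_spec <- function(duration_s, n_channels = 23, sample_rate_hz = 256,
                        background_amp_uv = 20, ictal_amp_uv = 100,
                        ictal_freq_hz = 3, channel_involvement = 0.8,
                        seed = 1L) {
  check_scalar_number(duration_s, "duration_s", positive = TRUE)
  check_scalar_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  check_scalar_number(background_amp_uv, "background_amp_uv", positive = TRUE)
  check_scalar_number(ictal_amp_uv, "ictal_amp_uv", positive = TRUE)
  if (ictal_amp_uv <= background_amp_uv) {
    stop_sdcae("ictal_amp_uv must exceed background_amp_uv",
               "sdcae_validation_error")
  }
  if (channel_involvement <= 0 || channel_involvement > 1) {
    stop_sdcae("channel_involvement must lie in (0, 1]",
               "sdcae_validation_error")
  }
  structure(list(duration_s = duration_s, n_channels = n_channels,
                 sample_rate_hz = sample_rate_hz,
                 background_amp_uv = background_amp_uv,
                 ictal_amp_uv = ictal_amp_uv,
                 ictal_freq_hz = ictal_freq_hz,
                 channel_involvement = channel_involvement,
                 seed = as.integer(seed)),
            class = "signal_spec")
}

validate_intervals <- function(seizures, duration_s) {
  if (is.null(seizures) || nrow(seizures) == 0) {
    return(data.frame(start_s = numeric(), end_s = numeric()))
  }
  seizures <- as.data.frame(seizures)
  if (any(seizures$end_s <= seizures$start_s)) {
    stop_sdcae("seizure intervals must have end_s > start_s",
               "sdcae_validation_error")
  }
  if (any(seizures$start_s < 0) || any(seizures$end_s > duration_s)) {
    stop_sdcae("seizure interval lies outside the recording",
               "sdcae_validation_error")
  }
  o <- order(seizures$start_s)
  seizures <- seizures[o, , drop = FALSE]
  if (nrow(seizures) > 1 &&
      any(seizures$start_s[-1] < seizures$end_s[-nrow(seizures)])) {
    stop_sdcae("seizure intervals must not overlap", "sdcae_validation_error")
  }
  rownames(seizures) <- NULL
  seizures
}

# 1/f-shaped Gaussian noise, one column per channel, unit RMS.
pink_noise <- function(n, n_channels) {
  white <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  spec <- stats::mvfft(white)
  freq <- c(0, seq_len(n - 1))
  freq <- pmin(freq, n - freq)               # two-sided frequency index
  w <- 1 / sqrt(pmax(freq, 1))
  shaped <- Re(stats::mvfft(spec * w, inverse = TRUE)) / n
  shaped <- sweep(shaped, 2, apply(shaped, 2, stats::sd), "/")
  shaped
}

#' Generate a synthetic EEG recording
#'
#' Produces a multichannel recording in which samples falling inside the
#' given seizure intervals carry a rhythmic high-amplitude spike-and-wave
#' component on a fraction of channels, superimposed on 1/f background
#' noise; all other samples contain background only.
#'
#' @param spec A [signal_spec()].
#' @param seizures Data frame with columns `start_s`, `end_s` (seconds from
#'   recording onset); may be empty or `NULL`.  Intervals must be
#'   non-overlapping and lie within the recording.
#' @param subject_id Subject label stored in the recording.
#' @param source_file Nominal file name stored in the recording (used to
#'   match annotations).
#' @return An `eeg_recording`: list with `subject_id`, `signal` (samples x
#'   channels matrix, microvolts), `sample_rate_hz`, `channel_names`,
#'   `source_file`.
#' @export
generate_recording <- function(spec, seizures = NULL, subject_id = "sub01",
                               source_file = paste0(subject_id, "_01.edf")) {
  stopifnot(inherits(spec, "signal_spec"))
  seizures <- validate_intervals(seizures, spec$duration_s)
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  nc <- spec$n_channels
  signal <- with_seed(spec$seed, {
    sig <- spec$background_amp_uv * pink_noise(n, nc)
    n_involved <- ceiling(spec$channel_involvement * nc)
    involved <- sample.int(nc, n_involved)
    phases <- stats::runif(nc, 0, 2 * pi)
    if (nrow(seizures) > 0) {
      tvec <- (seq_len(n) - 1) / fs
      for (r in seq_len(nrow(seizures))) {
        idx <- which(tvec >= seizures$start_s[r] & tvec < seizures$end_s[r])
        if (!length(idx)) next
        tt <- tvec[idx]
        for (ch in involved) {
          ph <- phases[ch]
          wav <- sin(2 * pi * spec$ictal_freq_hz * tt + ph) +
            0.5 * sin(2 * pi * 2 * spec$ictal_freq_hz * tt + 2 * ph) +
            0.25 * sin(2 * pi * 3 * spec$ictal_freq_hz * tt + 3 * ph)
          sig[idx, ch] <- sig[idx, ch] + spec$ictal_amp_uv * wav
        }
      }
    }
    sig
  })
  structure(list(subject_id = subject_id, signal = signal,
                 sample_rate_hz = fs,
                 channel_names = chbmit_channels()[seq_len(nc)],
                 source_file = source_file),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d samples x %d channels @ %g Hz (%s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal),
              x$sample_rate_hz, x$source_file))
  invisible(x)
}

#' Generate a toy cohort of annotated recordings
#'
#' Builds a deterministic multi-subject cohort for end-to-end exercising of
#' the pipeline.  Each subject receives a derived seed (`seed` + subject
#' index) and a recording in which every seizure lasts at least 15 s (so
#' none is removed by the 10-s minimum-duration filter).  Each seizure
#' occupies its own 120-s block, starting 30 s into the block, with a
#' duration drawn uniformly from 15-40 s.
#'
#' @param n_subjects,seizures_per_subject Counts (>= 1).
#' @param seed Integer master seed.
#' @param ... Overrides passed to [signal_spec()] (amplitudes, frequency,
#'   channel counts).
#' @return List with one element per subject, each a list with `recording`
#'   (an `eeg_recording`) and `annotations` (an `annotation_set`).
#' @export
make_toy_cohort <- function(n_subjects, seizures_per_subject, seed = 0L, ...) {
  if (n_subjects < 1 || seizures_per_subject < 1) {
    stop_sdcae("counts must be >= 1", "sdcae_validation_error")
  }
  lapply(seq_len(n_subjects), function(s) {
    sid <- sprintf("sub%02d", s)
    sseed <- as.integer(seed) + s
    duration <- 120 * seizures_per_subject + 60
    lens <- with_seed(sseed * 131 + 7,
                      stats::runif(seizures_per_subject, 15, 40))
    starts <- 120 * (seq_len(seizures_per_subject) - 1) + 30
    seiz <- data.frame(start_s = starts, end_s = round(starts + lens))
    spec <- signal_spec(duration_s = duration, seed = sseed, ...)
    rec <- generate_recording(spec, seiz, subject_id = sid)
    ann <- annotation_set(sid, data.frame(file = rec$source_file,
                                          start_s = seiz$start_s,
                                          end_s = seiz$end_s))
    list(recording = rec, annotations = ann)
  })
}
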