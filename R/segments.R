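# Segment extraction, class balancing, normalization, channel padding and
# stratified fold assignment.
#
# A segment is one non-overlapping (L x N) window of a recording,
# L = sample_rate * duration, N = 23 channels before padding.  Segment sets
# are stored sample-major: X has dimension (n_segments, L, N).

new_segment_set <- function(X, label, subject_id, start_s, duration_s,
                            sample_rate_hz) {
  structure(list(X = X, label = as.integer(label),
                 subject_id = subject_id, start_s = start_s,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %g s (%d ictal / %d interictal)\n",
              length(x$label), x$duration_s, sum(x$label == 1),
              sum(x$label == 0)))
  invisible(x)
}

segment_set_bind <- function(a, b) {
  stopifnot(a$duration_s == b$duration_s)
  X <- array(0, c(dim(a$X)[1] + dim(b$X)[1], dim(a$X)[2], dim(a$X)[3]))
  if (dim(a$X)[1] > 0) X[seq_len(dim(a$X)[1]), , ] <- a$X
  if (dim(b$X)[1] > 0) X[dim(a$X)[1] + seq_len(dim(b$X)[1]), , ] <- b$X
  new_segment_set(X, c(a$label, b$label), c(a$subject_id, b$subject_id),
                  c(a$start_s, b$start_s), a$duration_s, a$sample_rate_hz)
}

segment_set_subset <- function(s, idx) {
  new_segment_set(s$X[idx, , , drop = FALSE], s$label[idx], s$subject_id[idx],
                  s$start_s[idx], s$duration_s, s$sample_rate_hz)
}

#' Extract labeled segments from a recording
#'
#' Ictal segments tile each seizure interval from its start in
#' non-overlapping windows (the trailing partial window is dropped).
#' Interictal segments tile the recording from its start on a regular grid
#' and keep only windows with zero overlap with any seizure interval,
#' enlarged by an optional exclusion buffer.
#'
#' @param rec An `eeg_recording` (canonical 23-channel order).
#' @param ann An `annotation_set`, already filtered to seizures of at least
#'   the study's minimum duration.
#' @param duration_s Window length in seconds: 1, 2 or 4.
#' @param buffer_s Exclusion margin (seconds) around each seizure for
#'   interictal candidates.
#' @return List with `ictal` and `interictal` `segment_set`s.
#' @export
extract_segments <- function(rec, ann, duration_s, buffer_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!duration_s %in% c(1, 2, 4)) {
    stop_sdcae("duration must be 1, 2 or 4", "sdcae_validation_error")
  }
  fs <- rec$sample_rate_hz
  L <- as.integer(fs * duration_s)
  n <- nrow(rec$signal)
  nc <- ncol(rec$signal)
  total_s <- n / fs
  iv <- ann$intervals[ann$intervals$file == rec$source_file, , drop = FALSE]

  slice <- function(starts_s) {
    m <- length(starts_s)
    X <- array(0, c(m, L, nc))
    for (i in seq_len(m)) {
      s0 <- floor(starts_s[i] * fs)
      X[i, , ] <- rec$signal[(s0 + 1):(s0 + L), ]
    }
    X
  }

  ict_starts <- numeric()
  for (r in seq_len(nrow(iv))) {
    k <- floor((iv$end_s[r] - iv$start_s[r]) / duration_s)
    if (k > 0) {
      ict_starts <- c(ict_starts,
                      iv$start_s[r] + duration_s * (0:(k - 1)))
    }
  }
  ict_starts <- ict_starts[ict_starts + duration_s <= total_s]

  grid <- if (total_s < duration_s) numeric() else
    seq(0, total_s - duration_s, by = duration_s)
  keep <- rep(TRUE, length(grid))
  for (r in seq_len(nrow(iv))) {
    lo <- iv$start_s[r] - buffer_s
    hi <- iv$end_s[r] + buffer_s
    keep <- keep & (grid + duration_s <= lo | grid >= hi)
  }
  int_starts <- grid[keep]

  list(
    ictal = new_segment_set(slice(ict_starts),
                            rep(1L, length(ict_starts)),
                            rep(rec$subject_id, length(ict_starts)),
                            ict_starts, duration_s, fs),
    interictal = new_segment_set(slice(int_starts),
                                 rep(0L, length(int_starts)),
                                 rep(rec$subject_id, length(int_starts)),
                                 int_starts, duration_s, fs)
  )
}

#' Balance ictal and interictal segment counts
#'
#' Keeps every ictal segment and a seeded uniform without-replacement
#' sample of the interictal candidates of equal size, so both classes
#' contribute the same number of segments.
#'
#' @param ictal,interictal `segment_set`s.
#' @param seed Integer seed for the interictal draw.
#' @return A combined `segment_set` (ictal first, then the sampled
#'   interictal).
#' @export
balance_dataset <- function(ictal, interictal, seed = 1L) {
  n_ict <- length(ictal$label)
  n_int <- length(interictal$label)
  if (n_int < n_ict) {
    stop_sdcae(sprintf(
      "cannot balance: %d interictal candidates for %d ictal segments",
      n_int, n_ict), "sdcae_imbalance_error")
  }
  pick <- if (n_int == n_ict) seq_len(n_int) else
    with_seed(seed, sort(sample.int(n_int, n_ict)))
  segment_set_bind(ictal, segment_set_subset(interictal, pick))
}

#' Normalize a segment set
#'
#' Applies a single global z-score over all values of all segments and
#' channels jointly (`(x - mu) / sigma`, population standard deviation, so
#' a two-point dataset maps exactly to -1/+1), then a single global min-max
#' rescaling of the z-scores to \[0, 1\].  Both parameter pairs are
#' recorded so the transform is invertible.
#'
#' @param segments A `segment_set` (at least 2 segments, non-constant).
#' @param per_channel If `TRUE`, the z-score uses per-channel means and
#'   standard deviations instead of one global pair (the min-max step stays
#'   global).
#' @return List with `dataset` (a `segment_dataset` without fold
#'   assignments, values in \[0, 1\]) and `params` (`mu`, `sigma`, `min_z`,
#'   `max_z`).
#' @export
normalize_dataset <- function(segments, per_channel = FALSE) {
  stopifnot(inherits(segments, "segment_set"))
  if (length(segments$label) < 2) {
    stop_sdcae("need at least 2 segments to normalize",
               "sdcae_validation_error")
  }
  X <- segments$X
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  if (per_channel) {
    mu <- apply(X, 3, mean)
    sigma <- apply(X, 3, pop_sd)
    if (any(sigma == 0)) {
      stop_sdcae("constant channel: standard deviation is zero",
                 "sdcae_degenerate_error")
    }
    for (ch in seq_len(dim(X)[3])) {
      X[, , ch] <- (X[, , ch] - mu[ch]) / sigma[ch]
    }
  } else {
    mu <- mean(X)
    sigma <- pop_sd(as.vector(X))
    if (sigma == 0) {
      stop_sdcae("constant dataset: standard deviation is zero",
                 "sdcae_degenerate_error")
    }
    X <- (X - mu) / sigma
  }
  min_z <- min(X); max_z <- max(X)
  X <- (X - min_z) / (max_z - min_z)
  params <- list(mu = mu, sigma = sigma, min_z = min_z, max_z = max_z,
                 per_channel = per_channel)
  dataset <- structure(list(X = X, y = segments$label, norm = params,
                            fold = NULL,
                            meta = data.frame(
                              subject_id = segments$subject_id,
                              start_s = segments$start_s),
                            duration_s = segments$duration_s,
                            sample_rate_hz = segments$sample_rate_hz),
                       class = "segment_dataset")
  list(dataset = dataset, params = params)
}

#' @export
print.segment_dataset <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf(
    "<segment_dataset> %d segments of %g s: %d x %d x %d, %d ictal / %d interictal%s\n",
    d[1], x$duration_s, d[1], d[2], d[3], sum(x$y == 1), sum(x$y == 0),
    if (is.null(x$fold)) "" else sprintf(", %d folds", max(x$fold))))
  invisible(x)
}

#' Extend the channel dimension from 23 to 24
#'
#' Adds one column so the width halves cleanly through the pooling chain
#' (24 -> 12 -> 6 -> 3 -> 1).  The original 23 columns are unchanged.
#'
#' @param dataset A `segment_dataset` of width 23.
#' @param policy Content of the extra column: `"zeros"` (inert under
#'   convolution) or `"replicate-last"` (copies column 23).
#' @return The dataset with width 24.
#' @export
pad_channel_dim <- function(dataset, policy = c("zeros", "replicate-last")) {
  policy <- match.arg(policy)
  d <- dim(dataset$X)
  if (d[3] != 23L) {
    stop_sdcae(sprintf("expected width 23, got %d", d[3]),
               "sdcae_shape_error")
  }
  X <- array(0, c(d[1], d[2], 24L))
  X[, , 1:23] <- dataset$X
  if (policy == "replicate-last") X[, , 24] <- dataset$X[, , 23]
  dataset$X <- X
  dataset
}

#' Assign stratified cross-validation folds
#'
#' Partitions segment indices into `k` folds preserving the class balance:
#' within each class the fold sizes differ by at most one.
#'
#' @param labels 0/1 class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices (1..k), one per segment.
#' @export
assign_stratified_folds <- function(labels, k = 10, seed = 1L) {
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    stop_sdcae("both classes must be present", "sdcae_stratification_error")
  }
  counts <- table(labels)
  if (any(counts < k)) {
    stop_sdcae(sprintf("each class needs at least k = %d segments", k),
               "sdcae_stratification_error")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Build a balanced, normalized, fold-assigned dataset from a cohort
#'
#' Runs the full chain: per-recording segment extraction (with seizure
#' filtering), pooling across subjects, class balancing, global z-score +
#' min-max normalization, channel padding to width 24, and stratified fold
#' assignment.
#'
#' @param cohort List of `list(recording, annotations)` pairs, as returned
#'   by [make_toy_cohort()].
#' @param duration_s Segment length (1, 2 or 4 s).
#' @param seed Integer seed (balancing and fold assignment).
#' @param buffer_s Interictal exclusion buffer around seizures, seconds.
#' @param k Number of cross-validation folds.
#' @param min_seizure_s Minimum seizure duration retained.
#' @param pad_policy Channel padding policy, see [pad_channel_dim()].
#' @return A `segment_dataset` with `X` of dimension `(2K, L, 24)`,
#'   balanced labels `y`, normalization parameters and fold assignments.
#' @export
build_segment_dataset <- function(cohort, duration_s, seed = 1L,
                                  buffer_s = 0, k = 10, min_seizure_s = 10,
                                  pad_policy = "zeros") {
  ict <- NULL; int <- NULL
  for (subj in cohort) {
    ann <- filter_seizures(subj$annotations, min_seizure_s)
    segs <- extract_segments(subj$recording, ann, duration_s, buffer_s)
    ict <- if (is.null(ict)) segs$ictal else
      segment_set_bind(ict, segs$ictal)
    int <- if (is.null(int)) segs$interictal else
      segment_set_bind(int, segs$interictal)
  }
  balanced <- balance_dataset(ict, int, seed = seed)
  norm <- normalize_dataset(balanced)
  dataset <- pad_channel_dim(norm$dataset, policy = pad_policy)
  dataset$fold <- assign_stratified_folds(dataset$y, k = k, seed = seed + 1L)
  dataset
}
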