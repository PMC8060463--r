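# EDF reading/writing, summary-annotation parsing, channel
# canonicalization and seizure filtering.

test_that("EDF round trip preserves shape exactly and values to quantization", {
  rec <- toy_cohort()[[1]]$recording
  path <- tempfile()
  write_edf(rec, path)
  back <- read_edf(path, expected_sample_rate_hz = 256)
  expect_equal(dim(back$signal), dim(rec$signal))
  expect_identical(trimws(back$channel_names), rec$channel_names)
  # 16-bit quantization: half an LSB of the per-channel physical range
  lsb <- (2 * apply(abs(rec$signal), 2, max) * 1.0001) / 65535
  for (ch in c(1, 12, 23)) {
    expect_lt(max(abs(back$signal[, ch] - rec$signal[, ch])), lsb[ch])
  }
})

test_that("EDF values agree with an independent reader", {
  rec <- generate_recording(signal_spec(5, seed = 11),
                            data.frame(start_s = 1, end_s = 3))
  edf <- tempfile(fileext = ".edf")
  csv <- tempfile(fileext = ".csv")
  write_edf(rec, edf)
  ours <- read_edf(edf)
  utils::write.table(ours$signal, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste(
    "import mne, numpy as np",
    sprintf("raw = mne.io.read_raw_edf(%s, preload=True, verbose='error')",
            deparse(edf)),
    sprintf("ours = np.loadtxt(%s, delimiter=',')", deparse(csv)),
    "print('MAXDIFF', np.abs(raw.get_data().T * 1e6 - ours).max())",
    sep = "\n"))), stdout = TRUE, stderr = FALSE)
  diff <- as.numeric(sub("MAXDIFF ", "", grep("MAXDIFF", out, value = TRUE)))
  expect_lt(diff, 1e-9)
})

test_that("malformed EDF files are rejected", {
  rec <- toy_cohort()[[1]]$recording
  path <- tempfile()
  write_edf(rec, path)
  full <- readBin(path, raw(), file.size(path))
  trunc_path <- tempfile()
  writeBin(full[1:(length(full) %/% 2)], trunc_path)
  expect_error(read_edf(trunc_path), class = "sdcae_parse_error")
  expect_error(read_edf(tempfile("nope")), class = "sdcae_parse_error")

  # a 128 Hz file is readable but violates the pipeline's expectation
  slow <- generate_recording(signal_spec(4, sample_rate_hz = 128, seed = 1))
  slow_path <- tempfile()
  write_edf(slow, slow_path)
  expect_error(read_edf(slow_path, expected_sample_rate_hz = 256),
               class = "sdcae_format_error")
  expect_equal(read_edf(slow_path)$sample_rate_hz, 128)
})

test_that("summary parsing handles counts, pairs and malformed blocks", {
  path <- tempfile()
  writeLines(c(
    "Data Sampling Rate: 256 Hz", "",
    "File Name: chb01_03.edf",
    "Number of Seizures in File: 1",
    "Seizure Start Time: 2996 seconds",
    "Seizure End Time: 3036 seconds", "",
    "File Name: chb01_04.edf",
    "Number of Seizures in File: 0", "",
    "File Name: chb01_05.edf",
    "Number of Seizures in File: 2",
    "Seizure 1 Start Time: 100 seconds",
    "Seizure 1 End Time: 140 seconds",
    "Seizure 2 Start Time: 500 seconds",
    "Seizure 2 End Time: 520 seconds"), path)
  ann <- parse_summary(path)
  expect_s3_class(ann, "annotation_set")
  expect_equal(ann$subject_id, "chb01")
  expect_equal(nrow(ann$intervals), 3)
  first <- ann$intervals[ann$intervals$file == "chb01_03.edf", ]
  expect_equal(first$start_s, 2996)
  expect_equal(first$end_s, 3036)
  expect_equal(first$end_s - first$start_s, 40)
  expect_false("chb01_04.edf" %in% ann$intervals$file)

  bad <- tempfile()
  writeLines(c("File Name: chb02_01.edf",
               "Number of Seizures in File: 2",
               "Seizure Start Time: 10 seconds",
               "Seizure End Time: 30 seconds"), bad)
  expect_error(parse_summary(bad), class = "sdcae_parse_error")
})

test_that("summary write/parse round trip is faithful", {
  ann <- toy_cohort()[[2]]$annotations
  path <- tempfile()
  write_summary(ann, path)
  back <- parse_summary(path, subject_id = ann$subject_id)
  expect_equal(back$intervals, ann$intervals)
})

test_that("canonicalize_channels reorders, deduplicates and is idempotent", {
  rec <- toy_cohort()[[1]]$recording
  perm <- c(5:23, 1:4)
  shuffled <- rec
  shuffled$signal <- rec$signal[, perm]
  shuffled$channel_names <- rec$channel_names[perm]
  fixed <- canonicalize_channels(shuffled)
  canon <- chbmit_channels()
  for (j in c(1, 7, 23)) {
    src <- which(shuffled$channel_names == canon[j])[1]
    expect_identical(fixed$signal[, j], shuffled$signal[, src])
  }
  again <- canonicalize_channels(fixed)
  expect_identical(again$signal, fixed$signal)

  # duplicate label: first occurrence wins, width stays 23
  dup <- rec
  dup$channel_names[23] <- dup$channel_names[15]  # second "T8-P8" mimic
  got <- canonicalize_channels(dup)
  expect_equal(ncol(got$signal), 23)
  dup_cols <- which(chbmit_channels() == dup$channel_names[15])
  expect_identical(got$signal[, dup_cols[1]], got$signal[, dup_cols[2]])

  missing <- rec
  missing$channel_names[3] <- "BOGUS"
  expect_error(canonicalize_channels(missing),
               class = "sdcae_channel_error",
               regexp = chbmit_channels()[3])
})

test_that("filter_seizures applies the minimum-duration rule monotonically", {
  ann <- annotation_set("s", data.frame(file = "f.edf",
                                        start_s = c(0, 20),
                                        end_s = c(9, 40)))
  kept <- filter_seizures(ann)
  expect_equal(nrow(kept$intervals), 1)
  expect_equal(kept$intervals$start_s, 20)

  empty <- annotation_set("s", data.frame(file = character(),
                                          start_s = numeric(),
                                          end_s = numeric()))
  expect_equal(nrow(filter_seizures(empty)$intervals), 0)
  expect_equal(filter_seizures(ann, 0)$intervals, ann$intervals)

  # monotone: a larger threshold never keeps more intervals
  set.seed(1)
  iv <- data.frame(file = "f.edf", start_s = cumsum(runif(20, 31, 60)))
  iv$end_s <- iv$start_s + runif(20, 0.5, 30)
  rnd <- annotation_set("s", iv)
  counts <- vapply(c(0, 5, 10, 20, 40),
                   function(th) nrow(filter_seizures(rnd, th)$intervals), 0L)
  expect_true(all(diff(counts) <= 0))
})
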