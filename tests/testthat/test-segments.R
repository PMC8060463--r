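# Segment extraction geometry, balancing, normalization, padding and fold
# assignment.

make_rec <- function(duration_s, seed = 1, fs = 256) {
  generate_recording(signal_spec(duration_s, sample_rate_hz = fs,
                                 seed = seed),
                     NULL, subject_id = "s", source_file = "s_01.edf")
}

ann_for <- function(rec, start_s, end_s) {
  annotation_set("s", data.frame(file = rep(rec$source_file,
                                            length(start_s)),
                                 start_s = start_s, end_s = end_s))
}

test_that("ictal tiling anchors at seizure start and drops partial windows", {
  rec <- make_rec(60)
  segs <- extract_segments(rec, ann_for(rec, 10, 30), duration_s = 4)
  expect_equal(length(segs$ictal$label), 5)          # floor(20 / 4)
  expect_equal(segs$ictal$start_s, c(10, 14, 18, 22, 26))
  expect_equal(dim(segs$ictal$X)[2], 4 * 256)

  ten <- extract_segments(rec, ann_for(rec, 20, 30), duration_s = 4)
  expect_equal(length(ten$ictal$label), 2)           # floor(10 / 4)
})

test_that("a 2-s segment is 512 samples long", {
  rec <- make_rec(30)
  segs <- extract_segments(rec, ann_for(rec, 5, 17), duration_s = 2)
  expect_equal(dim(segs$ictal$X)[2:3], c(512, 23))
})

test_that("interictal candidates exclude seizure overlap exhaustively", {
  rec <- make_rec(600)
  segs <- extract_segments(rec, ann_for(rec, 100, 160), duration_s = 1)
  expect_equal(length(segs$ictal$label), 60)
  expect_equal(length(segs$interictal$label), 540)
  # no interictal window touches the seizure
  expect_true(all(segs$interictal$start_s + 1 <= 100 |
                    segs$interictal$start_s >= 160))
  # an exclusion buffer removes the flanking windows too
  buf <- extract_segments(rec, ann_for(rec, 100, 160), duration_s = 1,
                          buffer_s = 5)
  expect_equal(length(buf$interictal$label), 530)
})

test_that("recordings shorter than one window yield no segments", {
  rec <- make_rec(2)
  segs <- extract_segments(rec, ann_for(rec, numeric(), numeric()),
                           duration_s = 4)
  expect_equal(length(segs$ictal$label), 0)
  expect_equal(length(segs$interictal$label), 0)
})

test_that("balancing keeps all ictal plus an equal seeded interictal draw", {
  rec <- make_rec(600)
  segs <- extract_segments(rec, ann_for(rec, 100, 200), duration_s = 1)
  b1 <- balance_dataset(segs$ictal, segs$interictal, seed = 7)
  expect_equal(length(b1$label), 200)
  expect_equal(sum(b1$label == 1), 100)
  expect_equal(sum(b1$label == 0), 100)
  b2 <- balance_dataset(segs$ictal, segs$interictal, seed = 7)
  expect_identical(b1$X, b2$X)
  b3 <- balance_dataset(segs$ictal, segs$interictal, seed = 8)
  expect_false(identical(b1$start_s, b3$start_s))

  # equal counts pass through unchanged
  sub <- sdcae:::segment_set_subset(segs$interictal, 1:100)
  eq <- balance_dataset(segs$ictal, sub, seed = 1)
  expect_equal(sort(eq$start_s), sort(c(segs$ictal$start_s, sub$start_s)))

  expect_error(balance_dataset(segs$ictal,
                               sdcae:::segment_set_subset(segs$interictal,
                                                          1:10)),
               class = "sdcae_imbalance_error")
})

test_that("normalization is a global z-score followed by global min-max", {
  # two-point distribution {0, 10}: z-scores +-1, min-max {0, 1}
  X <- array(rep(c(0, 10), each = 8), c(2, 4, 2))
  s <- sdcae:::new_segment_set(X, c(0, 1), c("a", "a"), c(0, 1), 1, 4)
  res <- normalize_dataset(s)
  expect_equal(sort(unique(as.vector(res$dataset$X))), c(0, 1))
  expect_equal(res$params$mu, 5)
  expect_equal(res$params$min_z, -1, tolerance = 1e-12)

  cst <- sdcae:::new_segment_set(array(3, c(3, 4, 2)), c(0, 1, 0),
                                 rep("a", 3), 1:3, 1, 4)
  expect_error(normalize_dataset(cst), class = "sdcae_degenerate_error")

  # random set: recompute the chain directly
  set.seed(2)
  X <- array(rnorm(50 * 32 * 23, mean = 4, sd = 9), c(50, 32, 23))
  s <- sdcae:::new_segment_set(X, rep(0:1, 25), rep("a", 50),
                               seq_len(50), 1, 32)
  res <- normalize_dataset(s)
  z <- (res$dataset$X * (res$params$max_z - res$params$min_z)) +
    res$params$min_z
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  expect_equal(min(res$dataset$X), 0)
  expect_equal(max(res$dataset$X), 1)
})

test_that("channel padding extends width 23 to 24 per policy", {
  ds <- toy_dataset()        # already padded
  expect_equal(dim(ds$X)[3], 24)
  expect_equal(sum(ds$X[, , 24]), 0)

  raw <- list(X = array(runif(5 * 16 * 23), c(5, 16, 23)))
  pz <- pad_channel_dim(raw)
  expect_equal(dim(pz$X), c(5, 16, 24))
  expect_identical(pz$X[, , 1:23], raw$X)
  pr <- pad_channel_dim(raw, policy = "replicate-last")
  expect_identical(pr$X[, , 24], raw$X[, , 23])
  expect_error(pad_channel_dim(pz), class = "sdcae_shape_error")
})

test_that("stratified folds partition indices with per-class balance", {
  y <- rep(c(0, 1), each = 200)
  f <- assign_stratified_folds(y, k = 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  tab <- table(f, y)
  expect_true(all(tab == 20))

  y2 <- rep(c(0, 1), each = 101)
  f2 <- assign_stratified_folds(y2, k = 10, seed = 1)
  tab2 <- table(f2, y2)
  expect_true(all(tab2 %in% c(10, 11)))
  expect_equal(sum(tab2), 202)

  expect_error(assign_stratified_folds(rep(1, 20), k = 10),
               class = "sdcae_stratification_error")
  expect_error(assign_stratified_folds(c(rep(0, 5), rep(1, 50)), k = 10),
               class = "sdcae_stratification_error")
})

test_that("the assembled dataset satisfies its invariants deterministically", {
  ds <- toy_dataset()
  expect_equal(sum(ds$y == 1), sum(ds$y == 0))
  expect_gte(min(ds$X), 0)
  expect_lte(max(ds$X), 1)
  tab <- table(ds$fold, ds$y)
  expect_true(all(abs(tab - mean(tab)) <= 1))

  # no interictal segment overlaps a seizure interval
  for (subj in toy_cohort()) {
    iv <- subj$annotations$intervals
    sel <- ds$meta$subject_id == subj$recording$subject_id & ds$y == 0
    starts <- ds$meta$start_s[sel]
    for (r in seq_len(nrow(iv))) {
      expect_true(all(starts + ds$duration_s <= iv$start_s[r] |
                        starts >= iv$end_s[r]))
    }
  }

  ds2 <- build_segment_dataset(toy_cohort(), duration_s = 1, seed = 4)
  expect_identical(ds$X, ds2$X)
  expect_identical(ds$fold, ds2$fold)
})
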