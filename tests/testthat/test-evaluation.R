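# Confusion counts, the five metrics, cross-validation orchestration and
# the Kruskal-Wallis H test.

test_that("confusion counts follow the tie-goes-positive threshold rule", {
  c1 <- confusion_from_probs(c(1, 0), c(0.9, 0.1))
  expect_equal(unlist(c1[c("TP", "TN", "FP", "FN")]),
               c(TP = 1, TN = 1, FP = 0, FN = 0))

  tie <- confusion_from_probs(c(1, 0, 1), rep(0.5, 3))
  expect_equal(tie$FN, 0)      # ties predicted positive
  expect_equal(tie$FP, 1)
  expect_equal(tie$TN, 0)

  set.seed(30)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, 0.5)
    p <- runif(n)
    got <- confusion_from_probs(y, p, threshold = 0.4)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      pred <- p[j] >= 0.4
      if (pred && y[j] == 1) tp <- tp + 1
      if (pred && y[j] == 0) fp <- fp + 1
      if (!pred && y[j] == 1) fn <- fn + 1
      if (!pred && y[j] == 0) tn <- tn + 1
    }
    expect_equal(unlist(got[c("TP", "TN", "FP", "FN")]),
                 c(TP = tp, TN = tn, FP = fp, FN = fn))
  }
  expect_error(confusion_from_probs(c(1, 0), 0.5),
               class = "sdcae_shape_error")
})

test_that("the five metrics match their closed forms", {
  m <- compute_metrics(list(TP = 50, TN = 40, FP = 10, FN = 0))
  expect_equal(m[["accuracy"]], 90)
  expect_equal(m[["sensitivity"]], 100)
  expect_equal(m[["specificity"]], 80)
  expect_equal(m[["precision"]], 83.333, tolerance = 1e-4)
  expect_equal(m[["f1"]], 90.909, tolerance = 1e-4)

  perfect <- compute_metrics(list(TP = 7, TN = 9, FP = 0, FN = 0))
  expect_true(all(perfect == 100))

  warns <- testthat::capture_warnings(
    u <- compute_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0)))
  expect_true(all(grepl("undefined", warns)))
  expect_gte(length(warns), 2)
  expect_true(is.nan(u[["precision"]]))
  expect_true(is.nan(u[["sensitivity"]]))

  set.seed(31)
  for (i in 1:20) {
    cts <- as.list(rpois(4, 20) + 1)
    names(cts) <- c("TP", "TN", "FP", "FN")
    m <- compute_metrics(cts)
    expect_equal(m[["accuracy"]],
                 100 * (cts$TP + cts$TN) /
                   (cts$TP + cts$TN + cts$FP + cts$FN))
    expect_equal(m[["f1"]],
                 100 * 2 * (m[["precision"]] / 100) * (m[["sensitivity"]] / 100) /
                   (m[["precision"]] / 100 + m[["sensitivity"]] / 100))
    # accuracy decomposes over class-conditional rates
    P <- cts$TP + cts$FN; N <- cts$TN + cts$FP
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("class relabeling swaps sensitivity and specificity", {
  set.seed(32)
  y <- rbinom(40, 1, 0.5)
  p <- runif(40)
  a <- compute_metrics(confusion_from_probs(y, p, threshold = 0.5))
  # swap classes; mirror the threshold rule (ties flip side) by predicting
  # negative strictly above 1 - threshold
  b <- compute_metrics(confusion_from_probs(1 - y, 1 - p, threshold = 0.5))
  has_tie <- any(p == 0.5)
  if (!has_tie) {
    expect_equal(a[["sensitivity"]], b[["specificity"]])
    expect_equal(a[["specificity"]], b[["sensitivity"]])
  }
})

test_that("cross-validation aggregates exactly k folds per combination", {
  ds <- toy_dataset()
  oracle_trainer <- function(model, data, config) list(model = model)
  oracle_predictor <- function(model, data) as.numeric(data$y)
  cv <- cross_validate(ds, variants = c("DCAE_MLP", "DCNN_BiLSTM"),
                       train_config = training_config(epochs = 1),
                       model_opts = list(filter_scale = 16),
                       trainer = oracle_trainer,
                       predictor = oracle_predictor)
  expect_equal(nrow(cv$fold_metrics), 20)
  expect_true(all(cv$fold_metrics$accuracy == 100))
  expect_equal(cv$summary$accuracy_mean, c(100, 100))
  expect_equal(cv$summary$accuracy_sd, c(0, 0))

  no_folds <- ds; no_folds$fold <- NULL
  expect_error(cross_validate(no_folds, variants = "DCAE_MLP",
                              trainer = oracle_trainer,
                              predictor = oracle_predictor),
               class = "sdcae_config_error")
})

test_that("a scaled-down real cross-validation summarizes its folds", {
  ds <- toy_dataset()
  cv <- cross_validate(ds, variants = "DCNN_MLP",
                       train_config = training_config(epochs = 1, seed = 2),
                       model_opts = list(filter_scale = 16,
                                         mlp_units = c(8, 4)),
                       seed = 3)
  expect_equal(nrow(cv$fold_metrics), 10)
  for (m in c("accuracy", "sensitivity", "specificity")) {
    mu <- cv$summary[[paste0(m, "_mean")]]
    expect_gte(mu, min(cv$fold_metrics[[m]]))
    expect_lte(mu, max(cv$fold_metrics[[m]]))
  }
  expect_equal(cv$summary$accuracy_sd, stats::sd(cv$fold_metrics$accuracy))
})

test_that("kruskal_wallis reproduces hand-ranked values and conventions", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)
  expect_equal(kw$p_value, 0.04953, tolerance = 1e-4)
  expect_equal(kw$df, 1)

  same <- kruskal_wallis(list(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(same$H, 0, tolerance = 1e-12)

  flat <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(flat$H, 0)
  expect_equal(flat$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), class = "sdcae_validation_error")
  expect_error(kruskal_wallis(list(1:3, 5)), class = "sdcae_validation_error")
})

test_that("kruskal_wallis agrees with stats::kruskal.test on random groups", {
  set.seed(33)
  for (i in 1:25) {
    g <- sample(2:4, 1)
    groups <- lapply(seq_len(g), function(j) {
      round(rnorm(sample(3:8, 1), mean = j / 2), 1)  # induces ties
    })
    got <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               rep(seq_len(g), lengths(groups)))
    expect_equal(got$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("kruskal_wallis is invariant under monotone transformations", {
  set.seed(34)
  for (i in 1:10) {
    groups <- lapply(1:3, function(j) runif(5, 0, 10))
    h1 <- kruskal_wallis(groups)$H
    h2 <- kruskal_wallis(lapply(groups, function(x) exp(x / 3)))$H
    expect_equal(h1, h2, tolerance = 1e-12)
  }
})

test_that("reports lay out one row per duration-variant pair and round trip", {
  ds <- toy_dataset()
  oracle_trainer <- function(model, data, config) list(model = model)
  oracle_predictor <- function(model, data) as.numeric(data$y)
  cv <- cross_validate(ds, train_config = training_config(epochs = 1),
                       model_opts = list(filter_scale = 16),
                       trainer = oracle_trainer,
                       predictor = oracle_predictor)
  rep1 <- render_report(cv)
  expect_equal(nrow(rep1), 4)   # one duration x four variants
  expect_true(all(grepl("±", rep1$accuracy)))

  path <- tempfile(fileext = ".csv")
  render_report(cv, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), 4)
  expect_equal(back$accuracy_mean, rep1$accuracy_mean)

  jpath <- tempfile(fileext = ".json")
  render_report(cv, jpath)
  expect_true(jsonlite::validate(paste(readLines(jpath), collapse = "")))
})
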