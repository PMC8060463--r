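# Evaluation: confusion counts, the five metrics, cross-validation
# orchestration and the Kruskal-Wallis H test.

#' Confusion counts from predicted probabilities
#'
#' Predicts ictal (positive) when the probability is greater than or equal
#' to the threshold (ties go to the positive class) and tallies the
#' confusion matrix.
#'
#' @param y_true 0/1 labels (1 = ictal).
#' @param y_prob Predicted probabilities in \[0, 1\].
#' @param threshold Decision threshold.
#' @return List of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_from_probs <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    stop_sdcae("y_true and y_prob must have equal length", "sdcae_shape_error")
  }
  pred <- y_prob >= threshold
  pos <- y_true == 1
  structure(list(TP = sum(pred & pos), TN = sum(!pred & !pos),
                 FP = sum(pred & !pos), FN = sum(!pred & pos)),
            class = "confusion_counts")
}

#' The five classification metrics
#'
#' Accuracy, sensitivity (recall), specificity, precision and F1-score as
#' percentages, computed from confusion counts with ictal as the positive
#' class.  A zero denominator yields `NaN` with a warning rather than a
#' silent zero.
#'
#' @param counts A `confusion_counts` list (or any list with `TP`, `TN`,
#'   `FP`, `FN`).
#' @return Named numeric vector with `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, each in \[0, 100\].
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) {
    stop_sdcae("empty confusion counts", "sdcae_validation_error")
  }
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  acc <- (TP + TN) / total
  sens <- ratio(TP, TP + FN, "sensitivity")
  spec <- ratio(TN, TN + FP, "specificity")
  prec <- ratio(TP, TP + FP, "precision")
  f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) {
    warning("F1-score undefined: zero denominator", call. = FALSE)
    NaN
  } else {
    2 * prec * sens / (prec + sens)
  }
  c(accuracy = 100 * acc, sensitivity = 100 * sens, specificity = 100 * spec,
    precision = 100 * prec, f1 = 100 * f1)
}

dataset_fold_split <- function(dataset, fold) {
  test_idx <- which(dataset$fold == fold)
  train_idx <- which(dataset$fold != fold)
  subset_ds <- function(idx) {
    list(X = dataset$X[idx, , , drop = FALSE], y = dataset$y[idx])
  }
  list(train = subset_ds(train_idx), test = subset_ds(test_idx))
}

#' Stratified k-fold cross-validation over model variants
#'
#' For every (segment duration, model variant) combination and every fold,
#' trains a freshly initialized model on the other folds, evaluates the
#' five metrics on the held-out fold, and aggregates the per-fold metrics
#' as mean and standard deviation (sample, n-1 denominator).
#'
#' @param datasets A single `segment_dataset` or a list of them (one per
#'   segment duration), each carrying fold assignments.
#' @param variants Character vector of model variants to evaluate.
#' @param train_config A [training_config()].
#' @param model_opts List of extra arguments to [model_config()]
#'   (e.g. `filter_scale`, `lstm_units`, `mlp_units`).
#' @param seed Master seed; each (variant, fold) gets a derived seed so
#'   folds are trained from independent initializations.
#' @param trainer Training function `(model, data, config) -> list(model)`;
#'   the default is [train_model()].  Replaceable for testing.
#' @param predictor Prediction function `(model, data) -> probabilities`.
#' @param verbose Print progress.
#' @return List of class `cv_result` with `fold_metrics` (one row per
#'   duration/variant/fold) and `summary` (mean and sd per metric).
#' @export
cross_validate <- function(datasets, variants = MODEL_VARIANTS,
                           train_config = training_config(),
                           model_opts = list(), seed = 1L,
                           trainer = NULL, predictor = NULL,
                           verbose = FALSE) {
  if (inherits(datasets, "segment_dataset")) datasets <- list(datasets)
  trainer <- trainer %||% function(model, data, config) {
    train_model(model, data, config)
  }
  predictor <- predictor %||% function(model, data) {
    model_forward(model, as_training_tensors(data)$X, training = FALSE)$prob
  }
  rows <- list()
  for (dataset in datasets) {
    if (is.null(dataset$fold)) {
      stop_sdcae("dataset has no fold assignments", "sdcae_config_error")
    }
    k <- max(dataset$fold)
    for (variant in variants) {
      cfg <- do.call(model_config,
                     c(list(variant = variant,
                            duration_s = dataset$duration_s), model_opts))
      for (fold in seq_len(k)) {
        derived <- as.integer(seed) + 1000L * fold +
          7L * match(variant, MODEL_VARIANTS)
        split <- dataset_fold_split(dataset, fold)
        model <- build_model(cfg, seed = derived)
        fit_cfg <- train_config
        fit_cfg$seed <- derived + 1L
        fit <- trainer(model, split$train, fit_cfg)
        prob <- predictor(fit$model, split$test)
        met <- compute_metrics(confusion_from_probs(split$test$y, prob))
        rows[[length(rows) + 1]] <- cbind(
          data.frame(duration_s = dataset$duration_s, variant = variant,
                     fold = fold, seed = derived),
          as.data.frame(as.list(met)))
        if (verbose) {
          message(sprintf("%g s %-12s fold %2d: accuracy %.2f%%",
                          dataset$duration_s, variant, fold,
                          met[["accuracy"]]))
        }
      }
    }
  }
  fold_metrics <- do.call(rbind, rows)
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f1")
  summ <- do.call(rbind, lapply(
    split(fold_metrics,
          list(fold_metrics$duration_s, fold_metrics$variant), drop = TRUE),
    function(g) {
      out <- data.frame(duration_s = g$duration_s[1], variant = g$variant[1],
                        n_folds = nrow(g))
      for (m in metric_names) {
        out[[paste0(m, "_mean")]] <- mean(g[[m]])
        out[[paste0(m, "_sd")]] <- stats::sd(g[[m]])
      }
      out
    }))
  summ <- summ[order(summ$duration_s, summ$variant), ]
  rownames(summ) <- NULL
  structure(list(fold_metrics = fold_metrics, summary = summ),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>\n")
  print(render_report(x), row.names = FALSE)
  invisible(x)
}

#' Kruskal-Wallis H test
#'
#' Rank-based non-parametric comparison of two or more groups, with tie
#' correction and a chi-square approximation for the p-value
#' (`df = groups - 1`).  If all values across all groups are identical the
#' test degenerates to `H = 0`, `p = 1` by convention.
#'
#' @param groups List of numeric vectors (each of length >= 2).
#' @return List with the `H` statistic, `p_value` and `df`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 3.857
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_sdcae("need at least two groups", "sdcae_validation_error")
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    stop_sdcae("each group needs at least two values",
               "sdcae_validation_error")
  }
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(x)
  r <- rank(x)  # midranks for ties
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  H <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) {
    return(list(H = 0, p_value = 1, df = length(groups) - 1))
  }
  H <- H / tie_corr
  df <- length(groups) - 1
  list(H = H, p_value = stats::pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Render a cross-validation report table
#'
#' Lays out one row per (segment duration, model variant) with each metric
#' shown as `mean ± sd` over folds, plus the underlying numeric columns.
#'
#' @param cv A `cv_result` (or its `summary` data frame).
#' @param path Optional path; when given the table is also written as CSV
#'   (and, with a `.json` extension, as JSON).
#' @param digits Digits for the formatted `mean ± sd` strings.
#' @return Data frame with formatted and numeric metric columns.
#' @export
render_report <- function(cv, path = NULL, digits = 2) {
  summ <- if (inherits(cv, "cv_result")) cv$summary else cv
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f1")
  out <- summ[, c("duration_s", "variant")]
  for (m in metric_names) {
    mu <- summ[[paste0(m, "_mean")]]
    sdv <- summ[[paste0(m, "_sd")]]
    out[[m]] <- ifelse(
      is.na(mu) | is.nan(mu), "NA",
      sprintf(paste0("%.", digits, "f ± %.", digits, "f"), mu,
              ifelse(is.na(sdv), 0, sdv)))
  }
  out <- cbind(out, summ[, grep("_mean$|_sd$", names(summ), value = TRUE)])
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                           pretty = TRUE)
    } else {
      utils::write.csv(out, path, row.names = FALSE)
    }
  }
  out
}
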