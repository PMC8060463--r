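# Loss functions for joint reconstruction + classification training.

#' Binary cross-entropy classification loss
#'
#' `CL = -(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))` over a batch of
#' `N` segments.  Predicted probabilities are clipped to
#' `[eps, 1 - eps]` for numerical stability.
#'
#' @param y_true 0/1 labels.
#' @param y_pred Predicted probabilities in (0, 1).
#' @param eps Clipping constant.
#' @return Scalar loss.
#' @export
#' @examples
#' classification_loss(1, 0.5)  # -log(0.5)
classification_loss <- function(y_true, y_pred, eps = 1e-7) {
  if (length(y_true) != length(y_pred)) {
    stop_sdcae("y_true and y_pred must have equal length", "sdcae_shape_error")
  }
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' Mean-squared-error reconstruction loss
#'
#' Mean over segments of the per-segment mean squared difference between the
#' original `(m x n)` segment matrix and its reconstruction.
#'
#' @param X Original batch; array whose last dimension indexes segments, or
#'   a matrix for a single segment.
#' @param X_hat Reconstructed batch of identical shape.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(X, X_hat) {
  if (!identical(dim(X) %||% length(X), dim(X_hat) %||% length(X_hat))) {
    stop_sdcae("X and X_hat must have identical shapes", "sdcae_shape_error")
  }
  mean((X - X_hat)^2)
}

#' Total joint loss
#'
#' `TL = w_c * CL + w_r * RL`, the weighted sum of the classification and
#' reconstruction losses minimized by the autoencoder variants
#' (defaults `w_c = 0.5`, `w_r = 1`).
#'
#' @param CL Classification loss.
#' @param RL Reconstruction loss.
#' @param config A [training_config()] list (only `w_c` and `w_r` are used).
#' @return Scalar total loss.
#' @export
#' @examples
#' total_loss(0.6, 0.2, training_config())  # 0.5
total_loss <- function(CL, RL, config = training_config()) {
  config$w_c * CL + config$w_r * RL
}
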