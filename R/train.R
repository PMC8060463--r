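# Training: Adam optimization of the joint loss.

#' Training configuration
#'
#' Defaults are the full-scale reference protocol: 200 epochs, batch size 32, Adam
#' with learning rate 1e-4, loss weights `w_c = 0.5` (classification) and
#' `w_r = 1` (reconstruction).
#'
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param w_c,w_r Classification / reconstruction loss weights, in (0, 1].
#' @param beta1,beta2,adam_eps Adam moment decay rates and stability
#'   constant.
#' @param prob_clip_eps Probability clipping constant for the cross-entropy.
#' @param seed Integer seed for shuffling and dropout.
#' @return List of class `sdcae_training_config`.
#' @export
training_config <- function(epochs = 200, batch_size = 32,
                            learning_rate = 1e-4,
                            w_c = 0.5, w_r = 1,
                            beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-7,
                            prob_clip_eps = 1e-7, seed = 1L) {
  if (w_c <= 0 || w_c > 1 || w_r <= 0 || w_r > 1) {
    stop_sdcae("loss weights must lie in (0, 1]", "sdcae_config_error")
  }
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, w_c = w_c, w_r = w_r,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 prob_clip_eps = prob_clip_eps, seed = seed),
            class = "sdcae_training_config")
}

# ---- parameter addressing -------------------------------------------------

get_in <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

set_in <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1]]]] <- value
    return(x)
  }
  x[[path[[1]]]] <- set_in(x[[path[[1]]]], path[-1], value)
  x
}

# Enumerate every trainable parameter with its location in the model and in
# the gradient structure returned by model_backward().
param_addresses <- function(model) {
  out <- list()
  add <- function(mp, gp) out[[length(out) + 1]] <<- list(model = mp, grad = gp)
  for (nm in names(model$encoder)) {
    ty <- model$encoder[[nm]]$type
    if (ty == "conv") {
      add(list("encoder", nm, "K"), list("encoder", nm, "K"))
      add(list("encoder", nm, "b"), list("encoder", nm, "b"))
    } else if (ty == "bn") {
      add(list("encoder", nm, "gamma"), list("encoder", nm, "gamma"))
      add(list("encoder", nm, "beta"), list("encoder", nm, "beta"))
    }
  }
  for (nm in names(model$decoder %||% list())) {
    if (model$decoder[[nm]]$type == "conv") {
      add(list("decoder", nm, "K"), list("decoder", nm, "K"))
      add(list("decoder", nm, "b"), list("decoder", nm, "b"))
    }
  }
  if (model$head$type == "mlp") {
    for (i in seq_along(model$head$layers)) {
      add(list("head", "layers", i, "W"), list("head", paste0("dense", i), "W"))
      add(list("head", "layers", i, "b"), list("head", paste0("dense", i), "b"))
    }
  } else {
    for (dir in c("fwd", "bwd")) {
      for (g in c("W_f", "W_i", "W_o", "W_c", "b_f", "b_i", "b_o", "b_c")) {
        add(list("head", "params", dir, g), list("head", dir, g))
      }
    }
    add(list("head", "params", "W_out"), list("head", "dense_out", "W_out"))
    add(list("head", "params", "b_out"), list("head", "dense_out", "b_out"))
  }
  out
}

model_get_flat_params <- function(model, addresses = param_addresses(model)) {
  unlist(lapply(addresses, function(a) as.numeric(get_in(model, a$model))))
}

model_set_flat_params <- function(model, theta,
                                  addresses = param_addresses(model)) {
  pos <- 0L
  for (a in addresses) {
    cur <- get_in(model, a$model)
    n <- length(cur)
    val <- theta[pos + seq_len(n)]
    if (!is.null(dim(cur))) dim(val) <- dim(cur)
    model <- set_in(model, a$model, val)
    pos <- pos + n
  }
  stopifnot(pos == length(theta))
  model
}

# ---- loss + gradients on one batch ---------------------------------------

# Forward + backward on a batch.  X: (H, W, 1, B); y: 0/1 vector.
# For DCNN variants the loss is the plain classification loss.
model_loss_and_grads <- function(model, X, y, config, training = TRUE) {
  fw <- model_forward(model, X, training = training, keep_cache = TRUE)
  B <- length(y)
  p <- fw$prob
  CL <- classification_loss(y, p, eps = config$prob_clip_eps)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  dCL_dp <- -(y / pc - (1 - y) / (1 - pc)) / B
  joint <- !is.null(fw$recon)
  if (joint) {
    RL <- reconstruction_loss(X, fw$recon)
    TL <- total_loss(CL, RL, config)
    dprob <- config$w_c * dCL_dp
    dRecon <- config$w_r * 2 * (fw$recon - X) / length(X)
  } else {
    RL <- NA_real_
    TL <- CL
    dprob <- dCL_dp
    dRecon <- NULL
  }
  grads <- model_backward(fw$model, fw, dprob, dRecon)
  list(CL = CL, RL = RL, TL = TL, prob = p, grads = grads,
       model = fw$model)  # model carries updated batch-norm running stats
}

adam_init <- function(model, addresses) {
  lapply(addresses, function(a) {
    x <- get_in(model, a$model)
    list(m = array(0, dim(x) %||% length(x)),
         v = array(0, dim(x) %||% length(x)))
  })
}

adam_step <- function(model, grads, state, addresses, config, t) {
  lr <- config$learning_rate
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$adam_eps
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (k in seq_along(addresses)) {
    a <- addresses[[k]]
    g <- get_in(grads, a$grad)
    st <- state[[k]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    state[[k]] <- st
    cur <- get_in(model, a$model)
    upd <- cur - lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
    model <- set_in(model, a$model, upd)
  }
  list(model = model, state = state)
}

# Convert a dataset (segment_dataset or list(X, y)) to the internal batch
# tensor (H, W, 1, n) plus labels.
as_training_tensors <- function(dataset) {
  if (inherits(dataset, "segment_dataset")) {
    X <- dataset$X; y <- dataset$y
  } else {
    X <- dataset$X; y <- dataset$y
  }
  d <- dim(X)
  if (length(d) == 4L && d[4] == 1L) {
    d <- d[1:3]
    dim(X) <- d
  }
  # sample-major (n, H, W) -> internal (H, W, n, 1)
  Xb <- aperm(X, c(2, 3, 1))
  dim(Xb) <- c(d[2], d[3], d[1], 1L)
  list(X = Xb, y = as.numeric(y))
}

#' Train a model
#'
#' Optimizes the model with Adam over seeded shuffled mini-batches.
#' Autoencoder variants minimize the joint loss `TL = w_c*CL + w_r*RL`;
#' decoder-free variants minimize the classification loss alone.
#'
#' @param model An `sdcae_model` from [build_model()].
#' @param dataset Training data: a `segment_dataset`, or a list with `X`
#'   (array `n x H x 24`, values in \[0, 1\]) and `y` (0/1 labels).
#' @param config A [training_config()].
#' @param validation Optional dataset of the same form, evaluated in
#'   inference mode at the end of every epoch.
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` and `history`, a data frame with
#'   one row per epoch (accuracy and the CL/RL/TL losses; validation
#'   columns when `validation` is supplied).
#' @export
train_model <- function(model, dataset, config = training_config(),
                        validation = NULL, verbose = FALSE) {
  tr <- as_training_tensors(dataset)
  n <- length(tr$y)
  val <- if (!is.null(validation)) as_training_tensors(validation) else NULL
  addresses <- param_addresses(model)
  state <- adam_init(model, addresses)
  hist <- vector("list", config$epochs)
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- c(CL = 0, RL = 0, TL = 0)
      ep_n <- 0L
      ep_correct <- 0L
      for (s in starts) {
        ids <- perm[s:min(s + config$batch_size - 1L, n)]
        if (length(ids) < 2L) next  # batch norm needs >= 2 samples
        Xb <- tr$X[, , ids, , drop = FALSE]
        yb <- tr$y[ids]
        res <- model_loss_and_grads(model, Xb, yb, config, training = TRUE)
        if (!is.finite(res$TL)) {
          stop_sdcae(sprintf("training diverged to a non-finite loss at epoch %d",
                             epoch), "sdcae_training_error")
        }
        step <- step + 1L
        upd <- adam_step(res$model, res$grads, state, addresses, config, step)
        model <- upd$model
        state <- upd$state
        nb <- length(ids)
        ep_loss <- ep_loss + nb * c(res$CL, if (is.na(res$RL)) 0 else res$RL,
                                    res$TL)
        ep_correct <- ep_correct + sum((res$prob >= 0.5) == (yb == 1))
        ep_n <- ep_n + nb
      }
      row <- data.frame(epoch = epoch,
                        train_accuracy = ep_correct / ep_n,
                        CL = ep_loss[["CL"]] / ep_n,
                        RL = if (is.null(model$decoder)) NA_real_ else
                          ep_loss[["RL"]] / ep_n,
                        TL = ep_loss[["TL"]] / ep_n)
      if (!is.null(val)) {
        vf <- model_forward(model, val$X, training = FALSE)
        row$val_accuracy <- mean((vf$prob >= 0.5) == (val$y == 1))
        row$val_CL <- classification_loss(val$y, vf$prob,
                                          eps = config$prob_clip_eps)
        row$val_RL <- if (is.null(vf$recon)) NA_real_ else
          reconstruction_loss(val$X, vf$recon)
      }
      hist[[epoch]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  acc %.3f  TL %.5f", epoch,
                        row$train_accuracy, row$TL))
      }
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' Predict class probabilities
#'
#' @param object An `sdcae_model`.
#' @param newdata A dataset (`segment_dataset` or list with `X`).
#' @param ... Unused.
#' @return Numeric vector of ictal probabilities.
#' @export
predict.sdcae_model <- function(object, newdata, ...) {
  if (is.null(newdata$y)) newdata$y <- rep(0, dim(newdata$X)[1])
  tensors <- as_training_tensors(newdata)
  model_forward(object, tensors$X, training = FALSE)$prob
}
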