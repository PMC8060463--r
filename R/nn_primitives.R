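# Neural-network primitives.
#
# All internal tensor operations use arrays of dimension (H, W, B, C):
# time samples x channel width x batch x feature maps.  (Batch before
# feature maps lets every conv/batch-norm reshape be a plain `dim<-`
# change with no data movement.)  Convolutions use
# "same" padding at stride 1 with the TensorFlow convention for even kernel
# extents (pad_before = floor((k-1)/2), pad_after = k - 1 - pad_before), so
# a 3 x 2 kernel pads the time axis by (1, 1) and the width axis by (0, 1).

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`, the activation used by all hidden convolutional
#' and fully connected layers of the seizure-detection models.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with negative entries replaced by zero.
#' @export
#' @examples
#' relu(c(-3, 0, 2.5))
relu <- function(x) {
  pmax(x, 0)
}

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, used by the output units (class probability and the
#' reconstruction layer) and by the LSTM gates.
#'
#' @param x Numeric vector, matrix or array.
#' @return Values in (0, 1), same shape as `x`.
#' @export
#' @examples
#' sigmoid(0)  # 0.5
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

act_forward <- function(x, act) {
  switch(act,
    relu = relu(x),
    sigmoid = sigmoid(x),
    linear = x,
    stop_sdcae(paste0("unknown activation: ", act), "sdcae_config_error")
  )
}

# derivative of the activation given pre-activation `pre` and output `out`
act_grad <- function(dout, pre, out, act) {
  switch(act,
    relu = dout * (pre > 0),
    sigmoid = dout * out * (1 - out),
    linear = dout,
    stop_sdcae(paste0("unknown activation: ", act), "sdcae_config_error")
  )
}

same_pad <- function(k) {
  before <- (k - 1L) %/% 2L
  c(before, k - 1L - before)
}

# Build the im2col index matrix for a padded (Hp, Wp, B, C) array.
# Rows enumerate output positions (h fastest, then w, then b); columns
# enumerate kernel taps (dh fastest, then dw, then input channel), matching
# the natural flattening of a (kh, kw, C, Cout) kernel array.  Index
# matrices are cached per shape: every mini-batch of a training run reuses
# the same geometry.
im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C, B, kh, kw, Hp, Wp) {
  key <- paste(H, W, C, B, kh, kw, sep = "_")
  hit <- im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- rep.int(seq_len(H), times = W * B)
  w <- rep.int(rep(seq_len(W), each = H), times = B)
  b <- rep(seq_len(B), each = H * W)
  base <- h + Hp * ((w - 1L) + Wp * (b - 1L))
  dh <- rep.int(0L:(kh - 1L), times = kw * C)
  dw <- rep.int(rep(0L:(kw - 1L), each = kh), times = C)
  ci <- rep(0L:(C - 1L), each = kh * kw)
  off <- dh + Hp * (dw + Wp * B * ci)
  idx <- outer(base, off, `+`)
  if (length(im2col_cache) > 64) rm(list = ls(im2col_cache),
                                    envir = im2col_cache)
  im2col_cache[[key]] <- idx
  idx
}

pad_input <- function(X, ph, pw) {
  d <- dim(X)
  Hp <- d[1] + ph[1] + ph[2]
  Wp <- d[2] + pw[1] + pw[2]
  Xp <- array(0, c(Hp, Wp, d[3], d[4]))
  Xp[(ph[1] + 1):(ph[1] + d[1]), (pw[1] + 1):(pw[1] + d[2]), , ] <- X
  Xp
}

# Forward same-padded stride-1 convolution on an (H, W, B, C) array.
# Returns output plus the caches needed for backprop.
conv_forward <- function(X, K, b, act = "relu", keep_cache = FALSE) {
  d <- dim(X)
  kd <- dim(K)
  if (d[4] != kd[3]) {
    stop_sdcae("input channel count does not match kernel", "sdcae_shape_error")
  }
  H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  ph <- same_pad(kh); pw <- same_pad(kw)
  Xp <- pad_input(X, ph, pw)
  idx <- im2col_index(H, W, C, B, kh, kw, dim(Xp)[1], dim(Xp)[2])
  Xcol <- matrix(Xp[idx], nrow = H * W * B)
  Kmat <- matrix(K, nrow = kh * kw * C)
  pre <- Xcol %*% Kmat
  pre <- pre + rep(b, each = nrow(pre))
  out_mat <- act_forward(pre, act)
  out <- out_mat
  dim(out) <- c(H, W, B, Cout)
  cache <- NULL
  if (keep_cache) {
    cache <- list(Xcol = Xcol, pre = pre, out_mat = out_mat,
                  dims = c(H = H, W = W, C = C, B = B, kh = kh, kw = kw,
                           Cout = Cout),
                  ph = ph, pw = pw)
  }
  list(out = out, cache = cache)
}

conv_backward <- function(dOut, K, cache, act = "relu") {
  dm <- cache$dims
  H <- dm[["H"]]; W <- dm[["W"]]; C <- dm[["C"]]; B <- dm[["B"]]
  kh <- dm[["kh"]]; kw <- dm[["kw"]]; Cout <- dm[["Cout"]]
  dout_mat <- dOut
  dim(dout_mat) <- c(H * W * B, Cout)
  dpre <- act_grad(dout_mat, cache$pre, cache$out_mat, act)
  dK <- array(crossprod(cache$Xcol, dpre), dim(K))
  db <- colSums(dpre)
  # The input gradient is a correlation of dpre with the spatially flipped,
  # channel-transposed kernel, under the complementary padding.
  dpre_arr <- dpre
  dim(dpre_arr) <- c(H, W, B, Cout)
  Kf <- aperm(K[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
  ph <- cache$ph; pw <- cache$pw
  dPp <- pad_input(dpre_arr, c(ph[2], ph[1]), c(pw[2], pw[1]))
  idx <- im2col_index(H, W, Cout, B, kh, kw, dim(dPp)[1], dim(dPp)[2])
  dPcol <- matrix(dPp[idx], nrow = H * W * B)
  dX <- dPcol %*% matrix(Kf, nrow = kh * kw * Cout)
  dim(dX) <- c(H, W, B, C)
  list(dX = dX, dK = dK, db = db)
}

#' Same-padded 2-D convolution
#'
#' Stride-1 convolution with "same" zero padding, the building block of the
#' encoder and decoder networks.  Spatial dimensions are preserved; the
#' number of output feature maps equals the number of filters.
#'
#' @param input Numeric array `(H, W, C_in)` — a single example — or
#'   `(H, W, C_in, B)` for a batch.
#' @param kernel Numeric array `(kh, kw, C_in, C_out)`.
#' @param bias Numeric vector of length `C_out` (default zeros).
#' @param activation One of `"linear"` (default), `"relu"`, `"sigmoid"`.
#' @return Array `(H, W, C_out)` (or `(H, W, C_out, B)` for batched input).
#' @export
conv2d_same <- function(input, kernel, bias = NULL,
                        activation = c("linear", "relu", "sigmoid")) {
  activation <- match.arg(activation)
  single <- length(dim(input)) == 3L
  if (single) dim(input) <- c(dim(input), 1L)
  if (length(dim(input)) != 4L || length(dim(kernel)) != 4L) {
    stop_sdcae("input must be a 3-D or 4-D array, kernel 4-D",
               "sdcae_shape_error")
  }
  if (is.null(bias)) bias <- numeric(dim(kernel)[4])
  out <- conv_forward(aperm(input, c(1, 2, 4, 3)), kernel, bias,
                      act = activation)$out
  out <- aperm(out, c(1, 2, 4, 3))
  if (single) dim(out) <- dim(out)[1:3]
  out
}

pool_offsets <- function(p, q) {
  list(i = rep(seq_len(p), times = q), j = rep(seq_len(q), each = p))
}

maxpool_forward <- function(X, window, keep_cache = FALSE) {
  d <- dim(X)
  p <- window[1]; q <- window[2]
  if (d[1] %% p != 0 || d[2] %% q != 0) {
    stop_sdcae(sprintf("dimensions (%d, %d) not divisible by pool window (%d, %d)",
                       d[1], d[2], p, q), "sdcae_shape_error")
  }
  Ho <- d[1] %/% p; Wo <- d[2] %/% q
  off <- pool_offsets(p, q)
  cur <- X[seq(off$i[1], d[1], p), seq(off$j[1], d[2], q), , , drop = FALSE]
  win <- array(1L, dim(cur))
  if (length(off$i) > 1) {
    for (k in 2:length(off$i)) {
      sl <- X[seq(off$i[k], d[1], p), seq(off$j[k], d[2], q), , , drop = FALSE]
      better <- sl > cur              # strict: ties keep the earliest tap
      cur[better] <- sl[better]
      win[better] <- k
    }
  }
  cache <- NULL
  if (keep_cache) cache <- list(win = win, window = window, in_dim = d)
  list(out = cur, cache = cache)
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$in_dim
  p <- cache$window[1]; q <- cache$window[2]
  off <- pool_offsets(p, q)
  dX <- array(0, d)
  for (k in seq_along(off$i)) {
    sel <- cache$win == k
    if (any(sel)) {
      contrib <- array(0, dim(dOut))
      contrib[sel] <- dOut[sel]
      dX[seq(off$i[k], d[1], p), seq(off$j[k], d[2], q), , ] <- contrib
    }
  }
  dX
}

upsample_forward <- function(X, factor) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = factor[1]),
    rep(seq_len(d[2]), each = factor[2]), , , drop = FALSE]
}

upsample_backward <- function(dOut, factor) {
  d <- dim(dOut)
  Ho <- d[1] %/% factor[1]; Wo <- d[2] %/% factor[2]
  dX <- array(0, c(Ho, Wo, d[3], d[4]))
  for (j in seq_len(factor[2])) {
    for (i in seq_len(factor[1])) {
      dX <- dX + dOut[seq(i, d[1], factor[1]), seq(j, d[2], factor[2]), , ,
                      drop = FALSE]
    }
  }
  dX
}

#' Max pooling over non-overlapping windows
#'
#' Downsamples by taking the maximum over each `window`-sized block.  The
#' encoder uses (2, 2) windows after the first three convolutions and (2, 3)
#' after the last, reducing the 24-wide channel axis to 1.
#'
#' @param input Array `(H, W)`, `(H, W, C)` or `(H, W, C, B)`.
#' @param window Integer pair (rows, cols); both must divide the input.
#' @return Pooled array with the leading two dimensions divided by `window`.
#' @export
maxpool <- function(input, window) {
  nd <- length(dim(input) %||% integer())
  if (nd == 0L) stop_sdcae("input must be an array", "sdcae_shape_error")
  orig <- dim(input)
  if (nd == 2L) dim(input) <- c(orig, 1L, 1L)
  if (nd == 3L) dim(input) <- c(orig, 1L)
  out <- maxpool_forward(input, as.integer(window))$out
  if (nd == 2L) dim(out) <- dim(out)[1:2]
  if (nd == 3L) dim(out) <- dim(out)[1:3]
  out
}

#' Nearest-neighbour upsampling
#'
#' Repeats rows and columns by the given factors; the decoder's inverse of
#' max pooling.
#'
#' @param input Array `(H, W)`, `(H, W, C)` or `(H, W, C, B)`.
#' @param factor Integer pair (row factor, col factor).
#' @return Enlarged array.
#' @export
upsample <- function(input, factor) {
  nd <- length(dim(input) %||% integer())
  if (nd == 0L) stop_sdcae("input must be an array", "sdcae_shape_error")
  orig <- dim(input)
  if (nd == 2L) dim(input) <- c(orig, 1L, 1L)
  if (nd == 3L) dim(input) <- c(orig, 1L)
  out <- upsample_forward(input, as.integer(factor))
  if (nd == 2L) dim(out) <- dim(out)[1:2]
  if (nd == 3L) dim(out) <- dim(out)[1:3]
  out
}

# ---- batch normalization --------------------------------------------------

#' Batch-normalization parameter set
#'
#' @param n_features Number of features (feature maps) normalized
#'   independently.
#' @param eps Small stability constant added to the batch variance.
#' @param momentum Exponential-moving-average weight for the running
#'   statistics used at inference time.
#' @return List with learned scale `gamma`, shift `beta`, running mean and
#'   variance estimates, `eps` and `momentum`.
#' @export
batchnorm_params <- function(n_features, eps = 1e-3, momentum = 0.9) {
  check_scalar_number(eps, "eps", positive = TRUE)
  list(gamma = rep(1, n_features), beta = rep(0, n_features),
       running_mean = rep(0, n_features), running_var = rep(1, n_features),
       eps = eps, momentum = momentum)
}

#' Batch normalization
#'
#' Standardizes each feature using mini-batch statistics (training mode) or
#' running estimates (inference mode), then applies the learned scale
#' `gamma` and shift `beta`.
#'
#' @param x_batch Numeric matrix (batch x features) or vector (single
#'   feature).
#' @param params A [batchnorm_params()] list.
#' @param mode `"train"` (uses batch statistics, updates running estimates)
#'   or `"infer"`.
#' @return List with `out` (normalized batch, same shape as input) and
#'   `params` (with updated running statistics in training mode).
#' @export
#' @examples
#' bn <- batchnorm_params(1)
#' batchnorm(c(1, 2, 3), bn, mode = "train")$out
batchnorm <- function(x_batch, params, mode = c("train", "infer")) {
  mode <- match.arg(mode)
  vec <- is.null(dim(x_batch))
  if (vec) x_batch <- matrix(x_batch, ncol = 1)
  m <- nrow(x_batch)
  if (mode == "train") {
    if (m < 2) {
      stop_sdcae("batch normalization needs a batch of at least 2 in train mode",
                 "sdcae_validation_error")
    }
    mu <- colMeans(x_batch)
    vr <- colMeans(x_batch^2) - mu^2  # biased batch variance
    params$running_mean <- params$momentum * params$running_mean +
      (1 - params$momentum) * mu
    params$running_var <- params$momentum * params$running_var +
      (1 - params$momentum) * vr
  } else {
    mu <- params$running_mean
    vr <- params$running_var
  }
  xhat <- (x_batch - rep(mu, each = m)) / rep(sqrt(vr + params$eps), each = m)
  out <- xhat * rep(params$gamma, each = m) + rep(params$beta, each = m)
  if (vec) out <- drop(out)
  list(out = out, params = params)
}

# Internal conv-layer batch norm: per feature map over (H, W, B).
bn_conv_forward <- function(X, layer, training, keep_cache = FALSE) {
  d <- dim(X)
  M <- d[1] * d[2] * d[3]
  Xm <- X
  dim(Xm) <- c(M, d[4])  # (H*W*B) x C
  if (training) {
    if (d[3] < 2) {
      stop_sdcae("batch normalization needs batch size >= 2 in training",
                 "sdcae_validation_error")
    }
    mu <- colMeans(Xm)
    vr <- colMeans(Xm^2) - mu^2
    layer$running_mean <- layer$momentum * layer$running_mean +
      (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var +
      (1 - layer$momentum) * vr
  } else {
    mu <- layer$running_mean
    vr <- layer$running_var
  }
  invstd <- 1 / sqrt(vr + layer$eps)
  xhat <- (Xm - rep(mu, each = M)) * rep(invstd, each = M)
  out <- xhat * rep(layer$gamma, each = M) + rep(layer$beta, each = M)
  dim(out) <- d
  cache <- NULL
  if (keep_cache) {
    cache <- list(xhat = xhat, invstd = invstd, dims = d, train = training)
  }
  list(out = out, cache = cache, layer = layer)
}

bn_conv_backward <- function(dOut, layer, cache) {
  d <- cache$dims
  M <- d[1] * d[2] * d[3]
  dm <- dOut
  dim(dm) <- c(M, d[4])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * rep(layer$gamma, each = M)
  if (cache$train) {
    sx <- colSums(dxhat)
    sxx <- colSums(dxhat * cache$xhat)
    dXm <- (dxhat - rep(sx / M, each = M) -
              cache$xhat * rep(sxx / M, each = M)) *
      rep(cache$invstd, each = M)
  } else {
    dXm <- dxhat * rep(cache$invstd, each = M)
  }
  dX <- dXm
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- dense layers ---------------------------------------------------------

dense_forward <- function(X, W, b, act, keep_cache = FALSE) {
  pre <- X %*% W
  pre <- pre + rep(b, each = nrow(X))
  out <- act_forward(pre, act)
  cache <- NULL
  if (keep_cache) cache <- list(X = X, pre = pre, out = out)
  list(out = out, cache = cache)
}

dense_backward <- function(dOut, W, cache, act) {
  dpre <- act_grad(dOut, cache$pre, cache$out, act)
  list(dX = dpre %*% t(W),
       dW = crossprod(cache$X, dpre),
       db = colSums(dpre))
}

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = X, mask = NULL))
  }
  mask <- array(stats::runif(length(X)) >= rate, dim(X) %||% length(X))
  list(out = X * mask / (1 - rate), mask = mask / (1 - rate))
}
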