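# Model construction: the four architecture variants.
#
# DCAE_*  : convolutional encoder + decoder (autoencoder) + classifier head,
#           trained jointly on reconstruction and classification.
# DCNN_*  : the same encoder with the decoder removed, classification only.
# *_MLP   : flatten latent -> dense(50, relu) -> dense(32, relu) -> sigmoid.
# *_BiLSTM: latent reshaped to a (T x 64) sequence -> Bi-LSTM(50/direction)
#           -> time-average of concatenated outputs -> dropout -> sigmoid.

MODEL_VARIANTS <- c("DCAE_MLP", "DCAE_BiLSTM", "DCNN_MLP", "DCNN_BiLSTM")

#' Model configuration
#'
#' Describes one of the four architecture variants for a given segment
#' length.  Defaults reproduce the full-scale architecture: encoder filters
#' 32, 32, 64, 64; decoder filters 64, 32, 32, 1; 3 x 2 kernels; pooling
#' windows (2,2) x3 then (2,3); upsampling factors (2,3) then (2,2) x3; MLP
#' hidden sizes 50 and 32; 50 Bi-LSTM units per direction; dropout 0.1.
#'
#' @param variant One of `"DCAE_MLP"`, `"DCAE_BiLSTM"`, `"DCNN_MLP"`,
#'   `"DCNN_BiLSTM"`.
#' @param duration_s Segment length in seconds: 1, 2 or 4.
#' @param sample_rate_hz Samples per second (256 for this pipeline).
#' @param filter_scale Integer divisor applied to the convolutional filter
#'   counts (1 = full scale; 8 gives the reduced desk-scale models).  Must
#'   divide 32.
#' @param mlp_units Hidden sizes of the MLP head.
#' @param lstm_units Bi-LSTM cells per direction.
#' @param dropout Dropout rate on the Bi-LSTM output.
#' @return An object of class `sdcae_config`.
#' @export
model_config <- function(variant, duration_s,
                         sample_rate_hz = 256,
                         filter_scale = 1,
                         mlp_units = c(50, 32),
                         lstm_units = 50,
                         dropout = 0.1) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (!duration_s %in% c(1, 2, 4)) {
    stop_sdcae("duration must be 1, 2 or 4", "sdcae_config_error")
  }
  if (32 %% filter_scale != 0) {
    stop_sdcae("filter_scale must divide 32", "sdcae_config_error")
  }
  cfg <- list(
    variant = variant,
    duration_s = duration_s,
    sample_rate_hz = sample_rate_hz,
    encoder_filters = c(32, 32, 64, 64) %/% filter_scale,
    decoder_filters = c(64 %/% filter_scale, 32 %/% filter_scale,
                        32 %/% filter_scale, 1),
    kernel = c(3L, 2L),
    pools = list(c(2L, 2L), c(2L, 2L), c(2L, 2L), c(2L, 3L)),
    upsamples = list(c(2L, 3L), c(2L, 2L), c(2L, 2L), c(2L, 2L)),
    mlp_units = mlp_units,
    lstm_units = lstm_units,
    dropout = dropout,
    input_shape = c(duration_s * sample_rate_hz, 24L, 1L)
  )
  class(cfg) <- "sdcae_config"
  cfg
}

#' @export
print.sdcae_config <- function(x, ...) {
  cat(sprintf("<sdcae_config> %s, %g s segments (input %s)\n",
              x$variant, x$duration_s,
              paste(x$input_shape, collapse = " x ")))
  cat(sprintf("  encoder filters: %s | decoder filters: %s\n",
              paste(x$encoder_filters, collapse = ", "),
              paste(x$decoder_filters, collapse = ", ")))
  invisible(x)
}

#' Infer the layer-by-layer shape chain
#'
#' Propagates the input shape `(256 * duration_s, 24, 1)` through the
#' encoder (and the decoder for autoencoder variants), returning the output
#' shape of every convolution/pooling/upsampling stage.  The encoder
#' bottleneck (latent) shape is `(256 * duration_s / 16, 1, 64)` at full
#' filter scale.
#'
#' @param config A [model_config()] object.
#' @return Named list of integer shape vectors `(H, W, C)`; encoder stages
#'   are named `conv1..conv4` / `pool1..pool4`, decoder stages `up1..up4` /
#'   `deconv1..deconv4`; `latent` and `flatten` are included.
#' @export
infer_shapes <- function(config) {
  shp <- config$input_shape
  out <- list(input = shp)
  for (i in 1:4) {
    shp <- c(shp[1], shp[2], config$encoder_filters[i])
    out[[paste0("conv", i)]] <- shp
    p <- config$pools[[i]]
    if (shp[1] %% p[1] != 0 || shp[2] %% p[2] != 0) {
      stop_sdcae("pooling window does not divide the feature map",
                 "sdcae_config_error")
    }
    shp <- c(shp[1] %/% p[1], shp[2] %/% p[2], shp[3])
    out[[paste0("pool", i)]] <- shp
  }
  out$latent <- shp
  out$flatten <- prod(shp)
  if (startsWith(config$variant, "DCAE")) {
    for (i in 1:4) {
      u <- config$upsamples[[i]]
      shp <- c(shp[1] * u[1], shp[2] * u[2], shp[3])
      out[[paste0("up", i)]] <- shp
      shp <- c(shp[1], shp[2], config$decoder_filters[i])
      out[[paste0("deconv", i)]] <- shp
    }
    if (!all(shp == config$input_shape)) {
      stop_sdcae("decoder output shape does not match the input shape",
                 "sdcae_config_error")
    }
  }
  out
}

glorot_init <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Build a model
#'
#' Instantiates the computation graph for a configuration with seeded
#' fan-based uniform weight initialization.
#'
#' @param config A [model_config()] object.
#' @param seed Integer seed controlling initialization.
#' @return An object of class `sdcae_model` holding the encoder, decoder
#'   (autoencoder variants only) and classification-head parameters.
#' @export
build_model <- function(config, seed = 1L) {
  shapes <- infer_shapes(config)
  with_seed(seed, {
    kh <- config$kernel[1]; kw <- config$kernel[2]
    encoder <- list()
    cin <- config$input_shape[3]
    for (i in 1:4) {
      co <- config$encoder_filters[i]
      encoder[[paste0("conv", i)]] <- list(
        type = "conv", act = "relu",
        K = glorot_init(c(kh, kw, cin, co), kh * kw * cin, kh * kw * co),
        b = rep(0, co))
      bn <- batchnorm_params(co)
      encoder[[paste0("bn", i)]] <- c(list(type = "bn"), bn)
      encoder[[paste0("pool", i)]] <- list(type = "pool",
                                           window = config$pools[[i]])
      cin <- co
    }
    decoder <- NULL
    if (startsWith(config$variant, "DCAE")) {
      decoder <- list()
      for (i in 1:4) {
        decoder[[paste0("up", i)]] <- list(type = "up",
                                           factor = config$upsamples[[i]])
        co <- config$decoder_filters[i]
        act <- if (i == 4) "sigmoid" else "relu"
        decoder[[paste0("deconv", i)]] <- list(
          type = "conv", act = act,
          K = glorot_init(c(kh, kw, cin, co), kh * kw * cin, kh * kw * co),
          b = rep(0, co))
        cin <- co
      }
    }
    latent <- shapes$latent
    head <- if (endsWith(config$variant, "MLP")) {
      sizes <- c(shapes$flatten, config$mlp_units, 1)
      layers <- list()
      for (i in seq_len(length(sizes) - 1)) {
        act <- if (i == length(sizes) - 1) "sigmoid" else "relu"
        layers[[i]] <- list(
          W = glorot_init(c(sizes[i], sizes[i + 1]), sizes[i], sizes[i + 1]),
          b = rep(0, sizes[i + 1]), act = act)
      }
      list(type = "mlp", layers = layers)
    } else {
      list(type = "bilstm",
           params = bilstm_params(input_dim = latent[3],
                                  units = config$lstm_units,
                                  dropout = config$dropout))
    }
    model <- list(config = config, shapes = shapes, encoder = encoder,
                  decoder = decoder, head = head, seed = seed)
    class(model) <- "sdcae_model"
    model
  })
}

#' @export
print.sdcae_model <- function(x, ...) {
  print(x$config)
  m <- parameter_manifest(x)
  cat(sprintf("  %d parameter tensors, %d trainable parameters\n",
              nrow(m), sum(m$count)))
  invisible(x)
}

#' Parameter manifest
#'
#' @param model An `sdcae_model`.
#' @return Data frame listing every parameter tensor (component, layer,
#'   parameter name, shape, element count).
#' @export
parameter_manifest <- function(model) {
  rows <- list()
  add <- function(comp, layer, name, x) {
    rows[[length(rows) + 1]] <<- data.frame(
      component = comp, layer = layer, param = name,
      shape = paste(dim(x) %||% length(x), collapse = "x"),
      count = length(x), stringsAsFactors = FALSE)
  }
  for (nm in names(model$encoder)) {
    ly <- model$encoder[[nm]]
    if (ly$type == "conv") { add("encoder", nm, "K", ly$K); add("encoder", nm, "b", ly$b) }
    if (ly$type == "bn") { add("encoder", nm, "gamma", ly$gamma); add("encoder", nm, "beta", ly$beta) }
  }
  for (nm in names(model$decoder %||% list())) {
    ly <- model$decoder[[nm]]
    if (ly$type == "conv") { add("decoder", nm, "K", ly$K); add("decoder", nm, "b", ly$b) }
  }
  if (model$head$type == "mlp") {
    for (i in seq_along(model$head$layers)) {
      add("head", paste0("dense", i), "W", model$head$layers[[i]]$W)
      add("head", paste0("dense", i), "b", model$head$layers[[i]]$b)
    }
  } else {
    p <- model$head$params
    for (dir in c("fwd", "bwd")) {
      for (g in c("W_f", "W_i", "W_o", "W_c", "b_f", "b_i", "b_o", "b_c")) {
        add("head", paste0("bilstm_", dir), g, p[[dir]][[g]])
      }
    }
    add("head", "dense_out", "W", p$W_out)
    add("head", "dense_out", "b", p$b_out)
  }
  do.call(rbind, rows)
}

# Convert latent (T, 1, B, F) to a list of T matrices (B x F).
latent_to_seq <- function(L) {
  d <- dim(L)
  lapply(seq_len(d[1]), function(t) {
    matrix(L[t, 1, , ], nrow = d[3], ncol = d[4])
  })
}

#' Forward pass
#'
#' @param model An `sdcae_model`.
#' @param X Input batch, array `(H, 24, B, 1)` (or `(H, 24, B)`, in which
#'   case a singleton feature-map axis is appended), values in \[0, 1\].
#' @param training Logical; batch-statistics mode for batch norm and active
#'   dropout.  Training-mode calls also draw from the RNG (dropout), so for
#'   reproducibility wrap in a seeded context.
#' @param keep_cache Keep the intermediate values needed for backprop.
#' @return List with `prob` (length-B probability vector), `recon`
#'   (reconstruction array for autoencoder variants, else `NULL`), and
#'   internals (`latent`, caches, possibly updated batch-norm state in
#'   `model`).
#' @export
model_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  if (length(dim(X)) == 3L) {
    dim(X) <- c(dim(X), 1L)
  }
  if (!all(dim(X)[c(1, 2, 4)] == model$config$input_shape)) {
    stop_sdcae(sprintf("input shape (%s) does not match model input (%s)",
                       paste(dim(X)[c(1, 2, 4)], collapse = ","),
                       paste(model$config$input_shape, collapse = ",")),
               "sdcae_shape_error")
  }
  caches <- list(encoder = list(), decoder = list(), head = list())
  cur <- X
  for (nm in names(model$encoder)) {
    ly <- model$encoder[[nm]]
    if (ly$type == "conv") {
      r <- conv_forward(cur, ly$K, ly$b, act = ly$act, keep_cache = keep_cache)
      cur <- r$out; caches$encoder[[nm]] <- r$cache
    } else if (ly$type == "bn") {
      r <- bn_conv_forward(cur, ly, training, keep_cache = keep_cache)
      cur <- r$out; caches$encoder[[nm]] <- r$cache
      model$encoder[[nm]] <- modifyList(ly, r$layer[c("running_mean", "running_var")])
    } else if (ly$type == "pool") {
      r <- maxpool_forward(cur, ly$window, keep_cache = keep_cache)
      cur <- r$out; caches$encoder[[nm]] <- r$cache
    }
  }
  latent <- cur
  recon <- NULL
  if (!is.null(model$decoder)) {
    for (nm in names(model$decoder)) {
      ly <- model$decoder[[nm]]
      if (ly$type == "up") {
        caches$decoder[[nm]] <- dim(cur)
        cur <- upsample_forward(cur, ly$factor)
      } else {
        r <- conv_forward(cur, ly$K, ly$b, act = ly$act, keep_cache = keep_cache)
        cur <- r$out; caches$decoder[[nm]] <- r$cache
      }
    }
    recon <- cur
  }
  B <- dim(X)[3]
  if (model$head$type == "mlp") {
    flat <- matrix(aperm(latent, c(3, 1, 2, 4)), nrow = B)
    cur2 <- flat
    for (i in seq_along(model$head$layers)) {
      ly <- model$head$layers[[i]]
      r <- dense_forward(cur2, ly$W, ly$b, ly$act, keep_cache = keep_cache)
      cur2 <- r$out; caches$head[[paste0("dense", i)]] <- r$cache
    }
    prob <- drop(cur2)
    caches$head$flat <- if (keep_cache) flat else NULL
  } else {
    p <- model$head$params
    seq_in <- latent_to_seq(latent)
    Tn <- length(seq_in)
    fw <- lstm_seq_forward(seq_in, p$fwd, keep_cache = keep_cache)
    bw <- lstm_seq_forward(rev(seq_in), p$bwd, keep_cache = keep_cache)
    Hb <- rev(bw$H)
    concat_avg <- Reduce(`+`, lapply(seq_len(Tn), function(t) {
      cbind(fw$H[[t]], Hb[[t]])
    })) / Tn
    dr <- dropout_forward(concat_avg, p$dropout, training)
    r <- dense_forward(dr$out, p$W_out, p$b_out, "sigmoid",
                       keep_cache = keep_cache)
    prob <- drop(r$out)
    caches$head <- list(fw = fw$cache, bw = bw$cache, dr_mask = dr$mask,
                        dense = r$cache, Tn = Tn)
  }
  list(prob = prob, recon = recon, latent = latent, caches = caches,
       model = model)
}

# Backward pass.  dprob: gradient of the loss w.r.t. the output probability
# (length B); dRecon: gradient w.r.t. the reconstruction (or NULL).
# Returns gradients in the same nested structure as the model parameters.
model_backward <- function(model, fw, dprob, dRecon = NULL) {
  caches <- fw$caches
  grads <- list(encoder = list(), decoder = list(), head = list())
  B <- length(fw$prob)
  latent_dim <- dim(fw$latent)

  # head -> dLatent
  if (model$head$type == "mlp") {
    layers <- model$head$layers
    n <- length(layers)
    dcur <- matrix(dprob, ncol = 1)
    for (i in rev(seq_len(n))) {
      ly <- layers[[i]]
      r <- dense_backward(dcur, ly$W, caches$head[[paste0("dense", i)]], ly$act)
      grads$head[[paste0("dense", i)]] <- list(W = r$dW, b = r$db)
      dcur <- r$dX
    }
    dLat_head <- aperm(array(dcur, c(B, latent_dim[1], latent_dim[2],
                                     latent_dim[4])), c(2, 3, 1, 4))
  } else {
    p <- model$head$params
    hc <- caches$head
    r <- dense_backward(matrix(dprob, ncol = 1), p$W_out, hc$dense, "sigmoid")
    grads$head$dense_out <- list(W_out = r$dW, b_out = r$db)
    davg <- r$dX
    if (!is.null(hc$dr_mask)) davg <- davg * hc$dr_mask
    Tn <- hc$Tn
    U <- p$units
    dstep <- davg / Tn
    dHf <- lapply(seq_len(Tn), function(t) dstep[, seq_len(U), drop = FALSE])
    dHb_time <- lapply(seq_len(Tn), function(t) {
      dstep[, U + seq_len(U), drop = FALSE]
    })
    rf <- lstm_seq_backward(dHf, p$fwd, hc$fw)
    rb <- lstm_seq_backward(rev(dHb_time), p$bwd, hc$bw)
    grads$head$fwd <- rf$grads
    grads$head$bwd <- rb$grads
    dXb <- rev(rb$dXs)  # back to original time order
    dLat_head <- array(0, latent_dim)
    for (t in seq_len(Tn)) {
      dLat_head[t, 1, , ] <- rf$dXs[[t]] + dXb[[t]]
    }
  }

  dLatent <- dLat_head
  # decoder -> additional dLatent (autoencoder variants)
  if (!is.null(model$decoder) && !is.null(dRecon)) {
    dcur <- dRecon
    for (nm in rev(names(model$decoder))) {
      ly <- model$decoder[[nm]]
      if (ly$type == "conv") {
        r <- conv_backward(dcur, ly$K, caches$decoder[[nm]], act = ly$act)
        grads$decoder[[nm]] <- list(K = r$dK, b = r$db)
        dcur <- r$dX
      } else {
        dcur <- upsample_backward(dcur, ly$factor)
      }
    }
    dLatent <- dLatent + dcur
  }

  # encoder
  dcur <- dLatent
  for (nm in rev(names(model$encoder))) {
    ly <- model$encoder[[nm]]
    if (ly$type == "conv") {
      r <- conv_backward(dcur, ly$K, caches$encoder[[nm]], act = ly$act)
      grads$encoder[[nm]] <- list(K = r$dK, b = r$db)
      dcur <- r$dX
    } else if (ly$type == "bn") {
      r <- bn_conv_backward(dcur, ly, caches$encoder[[nm]])
      grads$encoder[[nm]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dcur <- r$dX
    } else {
      dcur <- maxpool_backward(dcur, caches$encoder[[nm]])
    }
  }
  grads
}
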