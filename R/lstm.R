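# LSTM cell and bidirectional sequence layer.
#
# The cell follows the standard gated formulation: forget, input and output
# gates are sigmoids of affine maps of the concatenated [h_{t-1}, x_t];
# the candidate state uses tanh; the cell state is
# c_t = f_t * c_{t-1} + i_t * ~c_t and the hidden state h_t = o_t * tanh(c_t).
# Weight matrices are (units x (units + input_dim)) acting on the
# concatenated column vector, biases have length `units`.

#' Create LSTM cell parameters
#'
#' @param units Number of memory cells.
#' @param input_dim Dimension of the per-step input.
#' @param init `"zero"` or `"glorot"` (uniform fan-based initialization).
#' @param forget_bias Initial value of the forget-gate bias; 1 keeps early
#'   gradients flowing (standard practice).
#' @return List with weight matrices `W_f`, `W_i`, `W_o`, `W_c` of shape
#'   `(units, units + input_dim)` and bias vectors `b_f`, `b_i`, `b_o`,
#'   `b_c`, plus `units` and `input_dim`.
#' @export
lstm_cell_params <- function(units, input_dim, init = c("zero", "glorot"),
                             forget_bias = 1) {
  init <- match.arg(init)
  nc <- units + input_dim
  mk <- function() {
    if (init == "zero") {
      matrix(0, units, nc)
    } else {
      lim <- sqrt(6 / (units + nc))
      matrix(stats::runif(units * nc, -lim, lim), units, nc)
    }
  }
  list(W_f = mk(), W_i = mk(), W_o = mk(), W_c = mk(),
       b_f = rep(forget_bias, units), b_i = rep(0, units),
       b_o = rep(0, units), b_c = rep(0, units),
       units = units, input_dim = input_dim)
}

#' One LSTM cell step
#'
#' Advances an LSTM memory cell by one time step given the current input
#' and the previous hidden and cell states.
#'
#' @param x_t Numeric input vector of length `input_dim`.
#' @param h_prev,c_prev Previous hidden and cell state vectors of length
#'   `units`.
#' @param params A [lstm_cell_params()] list.
#' @return List with the new hidden state `h` and cell state `c`.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, params) {
  if (length(x_t) != params$input_dim || length(h_prev) != params$units ||
      length(c_prev) != params$units) {
    stop_sdcae("lstm_cell_step: state/input dimensions do not match params",
               "sdcae_shape_error")
  }
  hx <- c(h_prev, x_t)
  f <- sigmoid(drop(params$W_f %*% hx) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% hx) + params$b_i)
  o <- sigmoid(drop(params$W_o %*% hx) + params$b_o)
  ctilde <- tanh(drop(params$W_c %*% hx) + params$b_c)
  c_t <- f * c_prev + i * ctilde
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t)
}

# Batched unidirectional pass.  X is a list of T matrices (B x F) in the
# order the direction consumes them.  Returns hidden states per step and a
# cache for BPTT.
lstm_seq_forward <- function(Xs, params, keep_cache = FALSE) {
  U <- params$units
  B <- nrow(Xs[[1]])
  Tn <- length(Xs)
  tWf <- t(params$W_f); tWi <- t(params$W_i)
  tWo <- t(params$W_o); tWc <- t(params$W_c)
  h <- matrix(0, B, U); cst <- matrix(0, B, U)
  Hs <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    hx <- cbind(h, Xs[[t]])
    f <- sigmoid(hx %*% tWf + rep(params$b_f, each = B))
    i <- sigmoid(hx %*% tWi + rep(params$b_i, each = B))
    o <- sigmoid(hx %*% tWo + rep(params$b_o, each = B))
    ctl <- tanh(hx %*% tWc + rep(params$b_c, each = B))
    c_prev <- cst
    cst <- f * c_prev + i * ctl
    tc <- tanh(cst)
    h <- o * tc
    Hs[[t]] <- h
    if (keep_cache) {
      cache[[t]] <- list(hx = hx, f = f, i = i, o = o, ctl = ctl,
                         c_prev = c_prev, c = cst, tc = tc)
    }
  }
  list(H = Hs, cache = cache)
}

# BPTT for one direction.  dHs: list of external gradients on each step's
# hidden output (B x U).  Returns input gradients per step and parameter
# gradients.
lstm_seq_backward <- function(dHs, params, cache) {
  U <- params$units
  Fd <- params$input_dim
  Tn <- length(cache)
  B <- nrow(dHs[[1]])
  dWf <- matrix(0, U, U + Fd); dWi <- dWf; dWo <- dWf; dWc <- dWf
  dbf <- rep(0, U); dbi <- dbf; dbo <- dbf; dbc <- dbf
  dXs <- vector("list", Tn)
  dh_next <- matrix(0, B, U)
  dc_next <- matrix(0, B, U)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- dHs[[t]] + dh_next
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    df <- dc * cc$c_prev
    di <- dc * cc$ctl
    dctl <- dc * cc$i
    dc_next <- dc * cc$f
    # through gate nonlinearities
    dzf <- df * cc$f * (1 - cc$f)
    dzi <- di * cc$i * (1 - cc$i)
    dzo <- do_ * cc$o * (1 - cc$o)
    dzc <- dctl * (1 - cc$ctl^2)
    dWf <- dWf + crossprod(dzf, cc$hx)
    dWi <- dWi + crossprod(dzi, cc$hx)
    dWo <- dWo + crossprod(dzo, cc$hx)
    dWc <- dWc + crossprod(dzc, cc$hx)
    dbf <- dbf + colSums(dzf)
    dbi <- dbi + colSums(dzi)
    dbo <- dbo + colSums(dzo)
    dbc <- dbc + colSums(dzc)
    dhx <- dzf %*% params$W_f + dzi %*% params$W_i +
      dzo %*% params$W_o + dzc %*% params$W_c
    dh_next <- dhx[, seq_len(U), drop = FALSE]
    dXs[[t]] <- dhx[, U + seq_len(Fd), drop = FALSE]
  }
  list(dXs = dXs,
       grads = list(W_f = dWf, W_i = dWi, W_o = dWo, W_c = dWc,
                    b_f = dbf, b_i = dbi, b_o = dbo, b_c = dbc))
}

#' Create bidirectional-LSTM classification head parameters
#'
#' @param input_dim Feature dimension of each sequence step.
#' @param units LSTM cells per direction.
#' @param dropout Dropout rate applied (training only) to the time-averaged
#'   concatenated output.
#' @param init Weight initialization scheme.
#' @return List with forward/backward cell parameter sets, the dense output
#'   weights, and the dropout rate.
#' @export
bilstm_params <- function(input_dim, units = 50, dropout = 0.1,
                          init = c("glorot", "zero")) {
  init <- match.arg(init)
  lim <- sqrt(6 / (2 * units + 1))
  W <- if (init == "zero") {
    matrix(0, 2 * units, 1)
  } else {
    matrix(stats::runif(2 * units, -lim, lim), 2 * units, 1)
  }
  list(fwd = lstm_cell_params(units, input_dim, init = init),
       bwd = lstm_cell_params(units, input_dim, init = init),
       W_out = W, b_out = 0, dropout = dropout, units = units,
       input_dim = input_dim)
}

#' Bidirectional-LSTM classification head
#'
#' Runs the latent sequence through two LSTM blocks in opposite directions,
#' concatenates the per-step outputs of both directions, averages them over
#' time, applies dropout (training mode only) and maps the result through a
#' single sigmoid unit to a class probability.
#'
#' @param latent_sequence Numeric matrix (T steps x F features).
#' @param params A [bilstm_params()] list.
#' @param training Logical; enables dropout.
#' @return Class probability in (0, 1).
#' @export
bilstm_head <- function(latent_sequence, params, training = FALSE) {
  if (is.null(dim(latent_sequence)) || nrow(latent_sequence) < 1) {
    stop_sdcae("latent sequence must be a non-empty T x F matrix",
               "sdcae_shape_error")
  }
  Tn <- nrow(latent_sequence)
  Xf <- lapply(seq_len(Tn), function(t) matrix(latent_sequence[t, ], nrow = 1))
  fw <- lstm_seq_forward(Xf, params$fwd)
  bw <- lstm_seq_forward(rev(Xf), params$bwd)
  Hb <- rev(bw$H)  # align backward outputs to original time order
  concat <- t(vapply(seq_len(Tn),
                     function(t) c(fw$H[[t]], Hb[[t]]),
                     numeric(2 * params$units)))
  if (Tn == 1) concat <- matrix(concat, nrow = 1)
  avg <- matrix(colMeans(concat), nrow = 1)
  avg <- dropout_forward(avg, params$dropout, training)$out
  drop(sigmoid(avg %*% params$W_out + params$b_out))
}
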