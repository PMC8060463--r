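# Shared fixtures, built once per test session.

fixture_env <- new.env(parent = emptyenv())

# Small two-subject cohort and its 1-s dataset, reused across test files.
toy_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    fixture_env$cohort <- make_toy_cohort(2, 2, seed = 0)
  }
  fixture_env$cohort
}

toy_dataset <- function() {
  if (is.null(fixture_env$dataset)) {
    fixture_env$dataset <- build_segment_dataset(toy_cohort(),
                                                 duration_s = 1, seed = 4)
  }
  fixture_env$dataset
}

with_seed_test <- function(seed, code) sdcae:::with_seed(seed, code)

# Brute-force same-padding convolution used as the independent oracle.
brute_conv2d <- function(X, K, b = numeric(dim(K)[4])) {
  d <- dim(X); kd <- dim(K)
  H <- d[1]; W <- d[2]; C <- d[3]
  kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  ph <- (kh - 1) %/% 2
  pw <- (kw - 1) %/% 2
  out <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (h in seq_len(H)) for (w in seq_len(W)) {
    s <- b[co]
    for (dh in 0:(kh - 1)) for (dw in 0:(kw - 1)) for (ci in seq_len(C)) {
      hi <- h + dh - ph
      wi <- w + dw - pw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        s <- s + X[hi, wi, ci] * K[dh + 1, dw + 1, ci, co]
      }
    }
    out[h, w, co] <- s
  }
  out
}

# Scalar re-implementation of one LSTM step, element by element.
scalar_lstm_step <- function(x, h0, c0, p) {
  U <- p$units
  hx <- c(h0, x)
  gate <- function(W, b, fun) {
    vapply(seq_len(U), function(u) fun(sum(W[u, ] * hx) + b[u]), 0)
  }
  sig <- function(z) 1 / (1 + exp(-z))
  f <- gate(p$W_f, p$b_f, sig)
  i <- gate(p$W_i, p$b_i, sig)
  o <- gate(p$W_o, p$b_o, sig)
  ct <- gate(p$W_c, p$b_c, tanh)
  cc <- f * c0 + i * ct
  list(h = o * tanh(cc), c = cc)
}

# Mean power of a signal in a frequency band, from the periodogram.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  sel <- freq >= lo & freq <= hi
  mean(sp[sel])
}
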