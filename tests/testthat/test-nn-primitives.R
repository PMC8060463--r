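# Activation functions, convolution, pooling, upsampling, batch
# normalization and the loss functions, each against direct evaluation.

test_that("relu and sigmoid satisfy their defining identities", {
  expect_equal(relu(c(-3, 0, 2.5)), c(0, 0, 2.5))
  expect_equal(sigmoid(0), 0.5)
  expect_lt(abs(sigmoid(30) - 1), 1e-12)
  set.seed(1)
  x <- rnorm(200, sd = 4)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 200), tolerance = 1e-12)
  expect_true(all(relu(x) >= 0))
  expect_equal(relu(x) - relu(-x), x)
})

test_that("conv2d_same matches the sliding-window oracle on random instances", {
  set.seed(10)
  for (i in 1:30) {
    H <- sample(3:8, 1); W <- sample(2:6, 1)
    C <- sample(1:3, 1); Cout <- sample(1:3, 1)
    X <- array(rnorm(H * W * C), c(H, W, C))
    K <- array(rnorm(3 * 2 * C * Cout), c(3, 2, C, Cout))
    b <- rnorm(Cout)
    expect_lt(max(abs(conv2d_same(X, K, b) - brute_conv2d(X, K, b))), 1e-10)
  }
  # identity kernel reproduces the input; zero kernel annihilates it
  X <- array(rnorm(6 * 4), c(6, 4, 1))
  K <- array(0, c(3, 2, 1, 1)); K[2, 1, 1, 1] <- 1
  expect_equal(conv2d_same(X, K), X)
  expect_equal(conv2d_same(X, array(0, c(3, 2, 1, 1))),
               array(0, c(6, 4, 1)))
  # relu / sigmoid activations are applied elementwise
  lin <- conv2d_same(X, K * 2)
  expect_equal(conv2d_same(X, K * 2, activation = "relu"), relu(lin))
  expect_equal(conv2d_same(X, K * 2, activation = "sigmoid"), sigmoid(lin))
})

test_that("maxpool takes window maxima and upsample repeats entries", {
  expect_equal(maxpool(matrix(c(1, 3, 2, 4), 2, 2), c(2, 2)),
               matrix(4, 1, 1))
  up <- upsample(matrix(5, 1, 1), c(2, 3))
  expect_equal(dim(up), c(2, 3))
  expect_true(all(up == 5))

  cst <- matrix(7, 4, 6)
  expect_equal(upsample(maxpool(cst, c(2, 3)), c(2, 3)), cst)

  set.seed(2)
  X <- array(rnorm(8 * 6 * 2), c(8, 6, 2))
  got <- maxpool(X, c(2, 3))
  for (ch in 1:2) for (i in 1:4) for (j in 1:2) {
    expect_equal(got[i, j, ch],
                 max(X[(2 * i - 1):(2 * i), (3 * j - 2):(3 * j), ch]))
  }
  u <- upsample(X, c(2, 2))
  expect_equal(u[2 * 3 - 1, 2 * 4, 1], X[3, 4, 1])
  expect_error(maxpool(X, c(3, 4)), class = "sdcae_shape_error")
})

test_that("batchnorm standardizes with batch statistics and learned affine", {
  bn <- batchnorm_params(1, eps = 1e-12)
  r <- batchnorm(c(1, 2, 3), bn, mode = "train")
  expect_equal(r$out, c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  bn2 <- batchnorm_params(2, eps = 1e-12)
  bn2$gamma <- c(0, 3); bn2$beta <- c(5, -1)
  x <- matrix(rnorm(20), 10, 2)
  out <- batchnorm(x, bn2, mode = "train")$out
  expect_equal(out[, 1], rep(5, 10))          # gamma = 0 collapses to beta
  expect_equal(mean(out[, 2]), -1, tolerance = 1e-9)
  expect_equal(mean(out[, 2]^2) - mean(out[, 2])^2, 9,
               tolerance = 1e-3)              # variance -> gamma^2

  expect_error(batchnorm(matrix(1, 1, 1), bn, mode = "train"),
               class = "sdcae_validation_error")

  # inference mode uses running estimates, not batch statistics
  bn3 <- batchnorm_params(1)
  bn3$running_mean <- 10; bn3$running_var <- 4
  r3 <- batchnorm(c(10, 12), bn3, mode = "infer")
  expect_equal(r3$out, c(0, 2 / sqrt(4 + bn3$eps)), tolerance = 1e-6)
})

test_that("losses match direct summation and the worked joint value", {
  expect_equal(classification_loss(1, 0.5), 0.693147, tolerance = 1e-6)
  expect_lt(classification_loss(c(0, 1), c(0, 1)), 1e-6)
  set.seed(3)
  for (i in 1:20) {
    y <- rbinom(8, 1, 0.5)
    p <- runif(8, 0.01, 0.99)
    manual <- -sum(y * log(p) + (1 - y) * log(1 - p)) / 8
    expect_lt(abs(classification_loss(y, p) - manual), 1e-12)
  }
  expect_error(classification_loss(c(1, 0), 0.5), class = "sdcae_shape_error")

  X <- array(0, c(4, 3, 5))
  expect_equal(reconstruction_loss(X, X), 0)
  expect_equal(reconstruction_loss(X, X + 0.5), 0.25)
  set.seed(4)
  A <- array(rnorm(60), c(4, 3, 5)); B <- array(rnorm(60), c(4, 3, 5))
  manual <- mean(vapply(1:5, function(i) mean((A[, , i] - B[, , i])^2), 0))
  expect_lt(abs(reconstruction_loss(A, B) - manual), 1e-12)
  expect_error(reconstruction_loss(A, array(0, c(3, 4, 5))),
               class = "sdcae_shape_error")

  cfg <- training_config()
  expect_equal(total_loss(0.6, 0.2, cfg), 0.5)
  expect_equal(total_loss(0.8, 0, cfg), 0.4)
  expect_equal(total_loss(1, 1, training_config(w_c = 1, w_r = 1)), 2)
  expect_error(training_config(w_c = 0), class = "sdcae_config_error")
})
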