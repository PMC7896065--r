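# Direct R implementation of padded strided convolution, used as the
# independent oracle for the compiled im2col path.
conv_oracle <- function(x, W4, b, stride, pad) {
  k <- dim(W4)[1]; cin <- dim(W4)[3]; cout <- dim(W4)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  oh <- (H + 2 * pad - k) %/% stride + 1
  ow <- (Wd + 2 * pad - k) %/% stride + 1
  xp <- array(0, dim = c(H + 2 * pad, Wd + 2 * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(Wd), ] <- x
  out <- array(0, dim = c(oh, ow, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      patch <- xp[(i - 1) * stride + seq_len(k),
                  (j - 1) * stride + seq_len(k), , drop = FALSE]
      out[i, j, co] <- sum(patch * W4[, , , co]) + b[co]
    }
  }
  out
}

# pack a (k, k, cin, cout) weight array into the engine's matrix layout
pack_weights <- function(W4) {
  k <- dim(W4)[1]; cin <- dim(W4)[3]; cout <- dim(W4)[4]
  m <- matrix(0, k * k * cin, cout)
  for (co in seq_len(cout)) {
    m[, co] <- as.numeric(aperm(W4[, , , co, drop = FALSE], c(1, 2, 3, 4)))
  }
  m
}

test_that("compiled convolution matches a direct R oracle", {
  set.seed(10)
  for (cfg in list(c(k = 3, s = 1, p = 1), c(k = 1, s = 1, p = 0),
                   c(k = 3, s = 2, p = 1), c(k = 7, s = 2, p = 3))) {
    x <- array(rnorm(12 * 10 * 3), dim = c(12, 10, 3))
    W4 <- array(rnorm(cfg[["k"]]^2 * 3 * 4),
                dim = c(cfg[["k"]], cfg[["k"]], 3, 4))
    b <- rnorm(4)
    got <- spectmets:::.conv_forward(x, pack_weights(W4), b,
                                     cfg[["k"]], cfg[["s"]], cfg[["p"]])
    expect_equal(got, conv_oracle(x, W4, b, cfg[["s"]], cfg[["p"]]),
                 tolerance = 1e-12)
  }
})

test_that("convolution gradients agree with finite differences", {
  set.seed(11)
  x <- array(rnorm(6 * 6 * 2), dim = c(6, 6, 2))
  W <- matrix(rnorm(3 * 3 * 2 * 3, 0, 0.5), 18, 3)
  b <- rnorm(3)
  dout <- array(rnorm(6 * 6 * 3), dim = c(6, 6, 3))
  loss <- function(W_, b_, x_) {
    sum(spectmets:::.conv_forward(x_, W_, b_, 3L, 1L, 1L) * dout)
  }
  g <- spectmets:::.conv_backward(x, W, dout, 3L, 1L, 1L)
  eps <- 1e-6
  for (idx in sample(length(W), 5)) {
    Wp <- W; Wp[idx] <- Wp[idx] + eps
    Wm <- W; Wm[idx] <- Wm[idx] - eps
    expect_equal(g$dW[idx], (loss(Wp, b, x) - loss(Wm, b, x)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (idx in sample(length(x), 5)) {
    xp <- x; xp[idx] <- xp[idx] + eps
    xm <- x; xm[idx] <- xm[idx] - eps
    expect_equal(g$dx[idx], (loss(W, b, xp) - loss(W, b, xm)) / (2 * eps),
                 tolerance = 1e-5)
  }
  expect_equal(as.numeric(g$db), apply(dout, 3, sum), tolerance = 1e-10)
})

test_that("max pooling matches a blockwise oracle and routes gradients", {
  set.seed(12)
  x <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
  r <- spectmets:::.maxpool_forward(x, 2L, 2L)
  for (c in 1:2) for (i in 1:4) for (j in 1:4) {
    expect_identical(r$out[i, j, c],
                     max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]))
  }
  dout <- array(1, dim = c(4, 4, 2))
  dx <- spectmets:::.maxpool_backward(r$argmax, dout, 8L, 8L)
  expect_equal(sum(dx), sum(dout))            # gradient mass conserved
  expect_identical(sum(dx != 0), 32L)         # one winner per window
})

test_that("average pooling averages full windows and distributes gradients", {
  x <- array(as.numeric(1:16), dim = c(4, 4, 1))
  out <- spectmets:::.avgpool_forward(x, 2L, 2L)
  expect_equal(out[1, 1, 1], mean(x[1:2, 1:2, 1]))
  dout <- array(4, dim = c(2, 2, 1))
  dx <- spectmets:::.avgpool_backward(dout, 2L, 2L, 4L, 4L)
  expect_true(all(dx == 1))
})

test_that("one epoch on eight images logs exactly one entry", {
  set.seed(13)
  imgs <- lapply(1:8, function(i) matrix(runif(32 * 32), 32, 32))
  labels <- rep(c("metastasis", "normal"), 4)
  spec <- build_vgg(7L, width_multiplier = 1 / 16,
                    input_shape = c(32L, 32L, 1L))
  net <- train_classifier(spec, imgs, labels,
                          train_config(epochs = 1L, batch_size = 4L), seed = 1L)
  expect_identical(nrow(net$training_log), 1L)
  expect_true(is.finite(net$training_log$loss))
})

test_that("training is deterministic given the seed", {
  imgs <- lapply(1:8, function(i) matrix(runif(32 * 32), 32, 32))
  labels <- rep(c("metastasis", "normal"), 4)
  spec <- build_vgg(7L, width_multiplier = 1 / 16,
                    input_shape = c(32L, 32L, 1L))
  n1 <- train_classifier(spec, imgs, labels, train_config(epochs = 2L), seed = 5L)
  n2 <- train_classifier(spec, imgs, labels, train_config(epochs = 2L), seed = 5L)
  expect_identical(n1$training_log, n2$training_log)
  expect_identical(predict_network(n1, imgs), predict_network(n2, imgs))
})

test_that("the regularized loss dominates the unregularized one", {
  # identical weights: L = e + lambda * sum(w^2) >= e, with equality only
  # at lambda = 0
  set.seed(14)
  w <- rnorm(100)
  e <- 0.83
  expect_gte(l2_loss(e, w, 0.01), l2_loss(e, w, 0))
  expect_identical(l2_loss(e, w, 0), e)
})

test_that("training reports divergence with the epoch index", {
  imgs <- lapply(1:4, function(i) matrix(runif(32 * 32) * 100, 32, 32))
  labels <- rep(c("metastasis", "normal"), 2)
  spec <- build_vgg(7L, width_multiplier = 1 / 16,
                    input_shape = c(32L, 32L, 1L))
  net <- build_network(spec, seed = 1L, init_sd = 5)
  expect_error(
    train_network(net, imgs, labels,
                  train_config(learning_rate = 1e6, epochs = 3L), seed = 1L),
    "diverged.*epoch")
})
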