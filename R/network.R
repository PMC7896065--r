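## ---------------------------------------------------------------------------
## Realization of a network_spec into weight arrays, forward inference and
## mini-batch gradient-descent training. Tensors are (h, w, c) arrays;
## convolution weights are (k*k*in_ch) x out_ch matrices matching the
## compiled im2col layout.
## ---------------------------------------------------------------------------

conv_dim <- function(n, k, stride, pad = 0L) (n + 2L * pad - k) %/% stride + 1L

init_conv <- function(in_ch, ly, init_sd) {
  fan_in <- ly$k * ly$k * in_ch
  sd <- if (is.null(init_sd)) sqrt(2 / fan_in) else init_sd
  list(type = "conv", k = ly$k, stride = ly$stride, pad = ly$pad,
       in_ch = in_ch, out_ch = ly$out,
       W = matrix(rnorm(fan_in * ly$out, 0, sd), fan_in, ly$out),
       b = numeric(ly$out))
}

init_fc <- function(in_n, out_n, init_sd) {
  sd <- if (is.null(init_sd)) sqrt(2 / in_n) else init_sd
  list(type = "fc", in_n = in_n, out_n = out_n,
       W = matrix(rnorm(in_n * out_n, 0, sd), out_n, in_n),
       b = numeric(out_n))
}

#' Realize an architecture into a weighted network
#'
#' Instantiates every layer of a [network_spec] with Gaussian-initialized
#' parameters (zero-mean normal draws, scaled by fan-in), reproducibly
#' from `seed`.
#'
#' @param spec a `network_spec` from [build_vgg()] and friends.
#' @param seed integer seed for the parameter draws.
#' @param init_sd fixed standard deviation for all parameter draws;
#'   `NULL` (default) uses fan-in scaling `sqrt(2 / fan_in)`.
#' @return A `network` object (realized layer list plus the spec).
#' @export
build_network <- function(spec, seed = 1L, init_sd = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  h <- spec$input_shape[1]; w <- spec$input_shape[2]; ch <- spec$input_shape[3]

  realize <- function(layers) {
    out <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      out[[i]] <- switch(ly$type,
        conv = {
          r <- init_conv(ch, ly, init_sd)
          h <<- conv_dim(h, ly$k, ly$stride, ly$pad)
          w <<- conv_dim(w, ly$k, ly$stride, ly$pad)
          ch <<- ly$out
          r
        },
        relu = list(type = "relu"),
        softmax = list(type = "softmax"),
        batchnorm = list(type = "batchnorm", gamma = rep(1, ch),
                         beta = rep(0, ch), mean = rep(0, ch),
                         var = rep(1, ch), eps = 1e-5),
        maxpool = {
          r <- list(type = "maxpool", k = ly$k, stride = ly$stride,
                    in_h = h, in_w = w)
          h <<- conv_dim(h, ly$k, ly$stride); w <<- conv_dim(w, ly$k, ly$stride)
          r
        },
        avgpool = {
          r <- list(type = "avgpool", k = ly$k, stride = ly$stride,
                    in_h = h, in_w = w)
          h <<- conv_dim(h, ly$k, ly$stride); w <<- conv_dim(w, ly$k, ly$stride)
          r
        },
        gap = {
          r <- list(type = "gap", in_h = h, in_w = w)
          h <<- 1L; w <<- 1L
          r
        },
        flatten = {
          r <- list(type = "flatten", in_n = h * w * ch)
          r
        },
        fc = {
          r <- init_fc(h * w * ch, ly$out, init_sd)
          h <<- 1L; w <<- 1L; ch <<- ly$out
          r
        },
        residual = {
          in_ch <- ch; in_h <- h; in_w <- w
          inner <- realize(ly$layers)
          proj <- NULL
          if (isTRUE(ly$projection)) {
            proj <- init_conv(in_ch, layer_conv(ly$out, k = 1L,
                                                stride = ly$stride, pad = 0L),
                              init_sd)
          }
          list(type = "residual", layers = inner, projection = proj)
        },
        dense_block = {
          units <- vector("list", ly$n_layers)
          for (u in seq_len(ly$n_layers)) {
            c_in <- ch
            bn1 <- list(type = "batchnorm", gamma = rep(1, c_in),
                        beta = rep(0, c_in), mean = rep(0, c_in),
                        var = rep(1, c_in), eps = 1e-5)
            cv1 <- init_conv(c_in, layer_conv(4L * ly$growth, k = 1L, pad = 0L),
                             init_sd)
            bn2 <- list(type = "batchnorm", gamma = rep(1, 4L * ly$growth),
                        beta = rep(0, 4L * ly$growth), mean = rep(0, 4L * ly$growth),
                        var = rep(1, 4L * ly$growth), eps = 1e-5)
            cv2 <- init_conv(4L * ly$growth, layer_conv(ly$growth, k = 3L), init_sd)
            units[[u]] <- list(bn1, list(type = "relu"), cv1,
                               bn2, list(type = "relu"), cv2)
            ch <<- ch + ly$growth
          }
          list(type = "dense_block", units = units, growth = ly$growth,
               concatenate = TRUE)
        },
        transition = {
          cv <- init_conv(ch, layer_conv(ly$out, k = 1L, pad = 0L), init_sd)
          ch <<- ly$out
          h <<- conv_dim(h, 2L, 2L); w <<- conv_dim(w, 2L, 2L)
          list(type = "transition", conv = cv)
        },
        stop("build_network: unknown layer type '", ly$type, "'")
      )
    }
    out
  }
  layers <- realize(spec$layers)
  structure(list(spec = spec, layers = layers,
                 out_shape = c(h, w, ch)), class = "network")
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("<network> %s: %d weight layers, %s parameters\n",
              x$spec$name, weight_layer_count(x$spec),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total parameter count of a realized network
#' @param net a `network`.
#' @return Integer-ish numeric.
#' @export
n_parameters <- function(net) {
  count <- function(layers) {
    s <- 0
    for (ly in layers) {
      if (ly$type %in% c("conv", "fc")) s <- s + length(ly$W) + length(ly$b)
      if (ly$type == "residual") {
        s <- s + count(ly$layers)
        if (!is.null(ly$projection)) s <- s + length(ly$projection$W) +
            length(ly$projection$b)
      }
      if (ly$type == "dense_block") s <- s + sum(vapply(ly$units, count, numeric(1)))
      if (ly$type == "transition") s <- s + length(ly$conv$W) + length(ly$conv$b)
    }
    s
  }
  count(net$layers)
}

as_input_tensor <- function(img, input_shape) {
  if (is.matrix(img)) {
    array(img, dim = c(nrow(img), ncol(img), 1L))
  } else {
    img
  }
}

apply_batchnorm <- function(x, ly) {
  d <- dim(x)
  scale <- ly$gamma / sqrt(ly$var + ly$eps)
  shift <- ly$beta - ly$mean * scale
  sweep(sweep(x, 3, scale, "*"), 3, shift, "+")
}

forward_layers <- function(x, layers) {
  for (ly in layers) {
    x <- switch(ly$type,
      conv = .conv_forward(x, ly$W, ly$b, ly$k, ly$stride, ly$pad),
      relu = relu(x),
      batchnorm = apply_batchnorm(x, ly),
      maxpool = .maxpool_forward(x, ly$k, ly$stride)$out,
      avgpool = .avgpool_forward(x, ly$k, ly$stride),
      gap = apply(x, 3, mean),
      flatten = as.numeric(x),
      fc = as.numeric(ly$W %*% as.numeric(x) + ly$b),
      softmax = { z <- x - max(x); exp(z) / sum(exp(z)) },
      residual = {
        inner <- forward_layers(x, ly$layers)
        shortcut <- if (is.null(ly$projection)) x else
          .conv_forward(x, ly$projection$W, ly$projection$b,
                        ly$projection$k, ly$projection$stride, ly$projection$pad)
        relu(inner + shortcut)
      },
      dense_block = {
        acc <- x
        for (unit in ly$units) {
          h <- forward_layers(acc, unit)
          acc <- if (isTRUE(ly$concatenate)) {
            array(c(acc, h), dim = c(dim(acc)[1], dim(acc)[2],
                                     dim(acc)[3] + dim(h)[3]))
          } else h  # ablation hook: plain chaining without concatenation
        }
        acc
      },
      transition = {
        z <- .conv_forward(x, ly$conv$W, ly$conv$b, ly$conv$k,
                           ly$conv$stride, ly$conv$pad)
        .avgpool_forward(z, 2L, 2L)
      },
      stop("forward: unknown layer type '", ly$type, "'")
    )
  }
  x
}

#' Forward pass: class probabilities for one image
#'
#' @param net a [build_network()] network.
#' @param img input image matrix (or `(h, w, c)` array) matching the
#'   spec's input shape.
#' @return Numeric probability vector over classes (softmax output,
#'   sums to 1).
#' @export
forward_network <- function(net, img) {
  x <- as_input_tensor(img, net$spec$input_shape)
  forward_layers(x, net$layers)
}

#' Class probabilities for a list of images
#'
#' @param net a `network`.
#' @param images list of input matrices.
#' @return `length(images) x n_classes` matrix of probabilities.
#' @export
predict_network <- function(net, images) {
  t(vapply(images, function(m) forward_network(net, m),
           numeric(net$spec$n_classes)))
}

## ---------------------------------------------------------------------------
## Training (sequential feed-forward networks: the VGG family)
## ---------------------------------------------------------------------------

seq_forward_cached <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    caches[[i]] <- switch(ly$type,
      conv = { out <- .conv_forward(x, ly$W, ly$b, ly$k, ly$stride, ly$pad)
               list(x = x, out = out) },
      relu = { out <- relu(x); list(mask = x > 0, out = out) },
      maxpool = { r <- .maxpool_forward(x, ly$k, ly$stride)
                  list(argmax = r$argmax, out = r$out) },
      avgpool = { out <- .avgpool_forward(x, ly$k, ly$stride)
                  list(out = out) },
      flatten = { list(in_dim = dim(x), out = as.numeric(x)) },
      fc = { v <- as.numeric(x)
             list(x = v, out = as.numeric(ly$W %*% v + ly$b)) },
      softmax = { z <- x - max(x); p <- exp(z) / sum(exp(z))
                  list(out = p) },
      stop("train: layer type '", ly$type,
           "' is not supported in sequential training")
    )
    x <- caches[[i]]$out
  }
  caches
}

# Backward from softmax + cross-entropy. `grad` starts as (p - onehot).
seq_backward <- function(layers, caches, grad) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; ca <- caches[[i]]
    if (ly$type == "conv") {
      r <- .conv_backward(ca$x, ly$W, grad, ly$k, ly$stride, ly$pad)
      grads[[i]] <- list(dW = r$dW, db = as.numeric(r$db))
      grad <- r$dx
    } else if (ly$type == "relu") {
      grad <- grad * ca$mask
    } else if (ly$type == "maxpool") {
      grad <- .maxpool_backward(ca$argmax, grad, ly$in_h, ly$in_w)
    } else if (ly$type == "avgpool") {
      grad <- .avgpool_backward(grad, ly$k, ly$stride, ly$in_h, ly$in_w)
    } else if (ly$type == "flatten") {
      grad <- array(grad, dim = ca$in_dim)
    } else if (ly$type == "fc") {
      grads[[i]] <- list(dW = outer(grad, ca$x), db = grad)
      grad <- as.numeric(t(ly$W) %*% grad)
    } else if (ly$type == "softmax") {
      # grad already holds dLoss/dlogits = p - y for cross-entropy
    }
    if (is.array(caches[[i]]$out)) caches[[i]]$out <- NULL
  }
  grads
}

#' Training configuration
#'
#' Defaults follow the reference protocol for this classification task:
#' mini-batch gradient descent (batch size 32) at learning rate 0.001.
#' The epoch budget is set per experiment.
#'
#' @param learning_rate step size.
#' @param batch_size mini-batch size.
#' @param epochs passes over the training set.
#' @param momentum classical momentum (0 = plain gradient descent).
#' @param shuffle reshuffle the training order each epoch.
#' @param verbose print per-epoch loss/accuracy.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L,
                         epochs = 500L, momentum = 0, shuffle = TRUE,
                         verbose = FALSE) {
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 shuffle = isTRUE(shuffle), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a sequential network by mini-batch gradient descent
#'
#' Supervised end-to-end training with softmax cross-entropy loss plus the
#' architecture's L2 weight penalty (`lambda_l2 * sum(w^2)`, see
#' [l2_loss()]). Supports the sequential feed-forward family
#' (convolution, ReLU, pooling, flatten, FC, softmax) -- i.e. the VGG
#' classifiers. Deterministic given `seed`.
#'
#' @param net a realized [build_network()] network (modified copy
#'   returned).
#' @param images list of input matrices.
#' @param labels integer class indices (1-based) or factor.
#' @param config a [train_config()].
#' @param seed seed for shuffling.
#' @return The trained `network`, with a `training_log` data.frame
#'   (epoch, loss, accuracy) attached.
#' @export
train_network <- function(net, images, labels, config = train_config(),
                          seed = 1L) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.integer(factor(labels))
  }
  n <- length(images)
  stopifnot(n == length(labels), n > 0L)
  k <- net$spec$n_classes
  lambda <- net$spec$lambda_l2
  layers <- net$layers
  vel <- vector("list", length(layers))   # momentum buffers
  log_rows <- vector("list", config$epochs)
  set.seed(seed)
  xs <- lapply(images, as_input_tensor, input_shape = net$spec$input_shape)

  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      bsz <- length(idx)
      acc_grads <- NULL
      for (ii in idx) {
        caches <- seq_forward_cached(layers, xs[[ii]])
        p <- caches[[length(caches)]]$out
        y <- labels[ii]
        ep_loss <- ep_loss - log(max(p[y], 1e-12))
        ep_correct <- ep_correct + (which.max(p) == y)
        g0 <- p; g0[y] <- g0[y] - 1
        grads <- seq_backward(layers, caches, g0)
        if (is.null(acc_grads)) {
          acc_grads <- grads
        } else {
          for (li in seq_along(grads)) {
            if (!is.null(grads[[li]])) {
              acc_grads[[li]]$dW <- acc_grads[[li]]$dW + grads[[li]]$dW
              acc_grads[[li]]$db <- acc_grads[[li]]$db + grads[[li]]$db
            }
          }
        }
      }
      for (li in seq_along(layers)) {
        if (is.null(acc_grads[[li]])) next
        dW <- acc_grads[[li]]$dW / bsz
        db <- acc_grads[[li]]$db / bsz
        if (lambda > 0) dW <- dW + 2 * lambda * layers[[li]]$W
        if (config$momentum > 0) {
          if (is.null(vel[[li]])) vel[[li]] <- list(W = dW * 0, b = db * 0)
          vel[[li]]$W <- config$momentum * vel[[li]]$W - config$learning_rate * dW
          vel[[li]]$b <- config$momentum * vel[[li]]$b - config$learning_rate * db
          layers[[li]]$W <- layers[[li]]$W + vel[[li]]$W
          layers[[li]]$b <- layers[[li]]$b + vel[[li]]$b
        } else {
          layers[[li]]$W <- layers[[li]]$W - config$learning_rate * dW
          layers[[li]]$b <- layers[[li]]$b - config$learning_rate * db
        }
      }
    }
    mean_loss <- ep_loss / n
    if (!is.finite(mean_loss)) {
      stop("train_network: training diverged (non-finite loss) at epoch ",
           epoch, call. = FALSE)
    }
    if (lambda > 0) {
      wsum <- sum(vapply(layers, function(ly) {
        if (!is.null(ly$W)) sum(ly$W^2) else 0
      }, numeric(1)))
      mean_loss <- l2_loss(mean_loss, numeric(0), 0) + lambda * wsum
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss = mean_loss,
                                    accuracy = ep_correct / n)
    if (config$verbose) {
      cat(sprintf("epoch %3d  loss %.4f  acc %.3f\n", epoch, mean_loss,
                  ep_correct / n))
    }
  }
  net$layers <- layers
  net$training_log <- do.call(rbind, log_rows)
  net
}
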