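#' Rectified linear unit
#'
#' `relu(x) = x` for `x >= 0`, else 0. Vectorized.
#' @param x numeric.
#' @return numeric of the same shape.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' L2-regularized loss
#'
#' `L = e + lambda * sum(w^2)`: the unregularized training error plus a
#' weight-decay penalty on the squared weights.
#'
#' @param e unregularized training error.
#' @param weights numeric vector/list of weight arrays.
#' @param lambda regularization strength, `>= 0`.
#' @return The penalized loss.
#' @export
l2_loss <- function(e, weights, lambda) {
  if (lambda < 0) stop("l2_loss: lambda must be >= 0", call. = FALSE)
  if (is.list(weights)) weights <- unlist(lapply(weights, as.numeric))
  e + lambda * sum(as.numeric(weights)^2)
}

## ---------------------------------------------------------------------------
## Declarative architecture descriptions
## ---------------------------------------------------------------------------

layer_conv <- function(out, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", out = as.integer(out), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}
layer <- function(type, ...) c(list(type = type), list(...))

network_spec <- function(family, name, layers, input_shape = c(256L, 256L, 1L),
                         n_classes = 2L, lambda_l2 = 0) {
  structure(list(family = family, name = name, layers = layers,
                 input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), lambda_l2 = lambda_l2),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s (%s): %d weight layers, input %s, %d classes\n",
              x$name, x$family, weight_layer_count(x),
              paste(x$input_shape, collapse = "x"), x$n_classes))
  invisible(x)
}

#' Count the weight layers of an architecture
#'
#' Weight layers are convolutional and fully-connected layers, counted
#' recursively through residual and dense blocks. Shortcut projection
#' convolutions and batch-normalization layers follow the usual
#' convention and are not counted.
#'
#' @param spec a `network_spec` (or a list of layer descriptors).
#' @return Integer count.
#' @export
weight_layer_count <- function(spec) {
  layers <- if (inherits(spec, "network_spec")) spec$layers else spec
  n <- 0L
  for (ly in layers) {
    n <- n + switch(ly$type,
      conv = 1L,
      fc = 1L,
      residual = weight_layer_count(ly$layers),
      dense_block = 2L * ly$n_layers,
      transition = 1L,
      0L)
  }
  n
}

vgg_conv_distribution <- function(variant) {
  switch(as.character(variant),
    "7"  = c(1L, 1L, 1L, 1L, 1L),
    "16" = c(2L, 2L, 3L, 3L, 3L),
    "19" = c(2L, 2L, 4L, 4L, 4L),
    "21" = c(3L, 3L, 4L, 4L, 4L),
    "24" = c(3L, 3L, 5L, 5L, 5L),
    stop("build_vgg: unknown variant ", variant,
         " (supported: 7, 16, 19, 21, 24)", call. = FALSE))
}

#' Build a VGG-style classifier architecture
#'
#' Five blocks of 3x3 convolutions (stride 1, padding 1) with channel
#' widths 64, 128, 256, 512, 512, each block closed by 2x2/stride-2 max
#' pooling, followed by the fully-connected head and a 2-way softmax. The
#' variant number equals the weight-layer count (convolutions plus FC
#' layers): the per-block convolution counts deepen from
#' (1,1,1,1,1) for VGG-7 through (2,2,3,3,3) for VGG-16, (2,2,4,4,4) for
#' VGG-19, (3,3,4,4,4) for VGG-21 and (3,3,5,5,5) for VGG-24. VGG-7
#' carries a single FC-4096 before the 2-way head (so its total is 7) and
#' uses L2 weight regularization by default; the deeper variants use the
#' standard FC-4096, FC-4096, FC-2 head.
#'
#' @param variant one of 7, 16, 19, 21, 24.
#' @param conv_distribution optional integer vector overriding the
#'   per-block convolution counts.
#' @param width_multiplier scales all channel widths (for scaled-down
#'   experiments).
#' @param input_shape `(height, width, channels)` of the input image.
#' @param lambda_l2 L2 regularization strength; defaults to 1e-4 for
#'   VGG-7 and 0 otherwise.
#' @param fc_sizes hidden FC widths before the 2-way head.
#' @return A `network_spec`.
#' @export
build_vgg <- function(variant, conv_distribution = NULL, width_multiplier = 1,
                      input_shape = c(256L, 256L, 1L), lambda_l2 = NULL,
                      fc_sizes = NULL) {
  dist <- if (is.null(conv_distribution)) vgg_conv_distribution(variant)
          else as.integer(conv_distribution)
  if (is.null(fc_sizes)) {
    fc_sizes <- if (as.integer(variant) == 7L) 4096L else c(4096L, 4096L)
  }
  if (is.null(lambda_l2)) lambda_l2 <- if (as.integer(variant) == 7L) 1e-4 else 0
  widths <- pmax(1L, as.integer(round(c(64, 128, 256, 512, 512) * width_multiplier)))
  fc_sizes <- pmax(2L, as.integer(round(fc_sizes * width_multiplier)))
  layers <- list()
  for (b in seq_along(dist)) {
    for (i in seq_len(dist[b])) {
      layers <- c(layers, list(layer_conv(widths[b]), layer("relu")))
    }
    layers <- c(layers, list(layer("maxpool", k = 2L, stride = 2L)))
  }
  layers <- c(layers, list(layer("flatten")))
  for (f in fc_sizes) {
    layers <- c(layers, list(layer("fc", out = f), layer("relu")))
  }
  layers <- c(layers, list(layer("fc", out = 2L), layer("softmax")))
  spec <- network_spec("vgg", paste0("VGG-", variant), layers,
                       input_shape = input_shape, lambda_l2 = lambda_l2)
  stopifnot(weight_layer_count(spec) == as.integer(variant))
  spec
}

#' Build the ResNet-34 classifier architecture
#'
#' Sixteen two-convolution residual modules in groups of (3, 4, 6, 3)
#' with channel widths 64, 128, 256, 512; each module adds its input (via
#' an identity shortcut, or a 1x1 projection when shape changes) to the
#' output of its two 3x3 convolutions. A 3x3 stem convolution and a
#' 3x3/stride-2 max pooling precede the groups; a 2x2/stride-1 average
#' pooling and global average pooling feed the 2-way FC head.
#'
#' @param width_multiplier scales channel widths.
#' @param input_shape input dimensions.
#' @return A `network_spec` with 34 weight layers.
#' @export
build_resnet34 <- function(width_multiplier = 1, input_shape = c(256L, 256L, 1L)) {
  widths <- pmax(1L, as.integer(round(c(64, 128, 256, 512) * width_multiplier)))
  counts <- c(3L, 4L, 6L, 3L)
  layers <- list(layer_conv(widths[1], k = 3L, stride = 2L), layer("batchnorm"),
                 layer("relu"),
                 layer("maxpool", k = 3L, stride = 2L))
  in_ch <- widths[1]
  for (g in seq_along(counts)) {
    for (i in seq_len(counts[g])) {
      stride <- if (g > 1L && i == 1L) 2L else 1L
      project <- stride != 1L || in_ch != widths[g]
      inner <- list(layer_conv(widths[g], k = 3L, stride = stride),
                    layer("batchnorm"), layer("relu"),
                    layer_conv(widths[g], k = 3L), layer("batchnorm"))
      layers <- c(layers, list(layer("residual", out = widths[g],
                                     stride = stride, projection = project,
                                     layers = inner)))
      in_ch <- widths[g]
    }
  }
  layers <- c(layers, list(layer("avgpool", k = 2L, stride = 1L),
                           layer("gap"), layer("flatten"),
                           layer("fc", out = 2L), layer("softmax")))
  spec <- network_spec("resnet", "ResNet-34", layers, input_shape = input_shape)
  stopifnot(weight_layer_count(spec) == 34L)
  spec
}

#' Build the DenseNet-121 classifier architecture
#'
#' A 7x7/stride-2 stem convolution and 3x3/stride-2 max pooling, four
#' dense blocks of (6, 12, 24, 16) two-convolution units (1x1 bottleneck
#' of width `4 * growth`, then 3x3 of width `growth`), joined by
#' transition layers (1x1 convolution halving the channels, then
#' 2x2/stride-2 average pooling), closed by global average pooling and
#' the 2-way FC head. Within a dense block every unit receives the
#' concatenation of the block input and all preceding units' outputs, so
#' a block entered with `c` channels exits with `c + n_layers * growth`.
#'
#' @param growth growth rate `k` (feature maps added per unit).
#' @param width_multiplier scales the stem width and growth rate.
#' @param input_shape input dimensions.
#' @return A `network_spec` with 121 weight layers.
#' @export
build_densenet121 <- function(growth = 32L, width_multiplier = 1,
                              input_shape = c(256L, 256L, 1L)) {
  growth <- max(1L, as.integer(round(growth * width_multiplier)))
  stem <- max(2L, as.integer(round(64 * width_multiplier)))
  block_sizes <- c(6L, 12L, 24L, 16L)
  layers <- list(layer_conv(stem, k = 7L, stride = 2L, pad = 3L),
                 layer("batchnorm"), layer("relu"),
                 layer("maxpool", k = 3L, stride = 2L))
  ch <- stem
  for (b in seq_along(block_sizes)) {
    layers <- c(layers, list(layer("dense_block", n_layers = block_sizes[b],
                                   growth = growth)))
    ch <- ch + block_sizes[b] * growth
    if (b < length(block_sizes)) {
      ch <- ch %/% 2L
      layers <- c(layers, list(layer("transition", out = ch)))
    }
  }
  layers <- c(layers, list(layer("batchnorm"), layer("relu"),
                           layer("gap"), layer("flatten"),
                           layer("fc", out = 2L), layer("softmax")))
  spec <- network_spec("densenet", "DenseNet-121", layers,
                       input_shape = input_shape)
  stopifnot(weight_layer_count(spec) == 121L)
  spec
}

#' Build any of the seven classifier architectures by name
#'
#' @param arch one of `"v7"`, `"v16"`, `"v19"`, `"v21"`, `"v24"`,
#'   `"r34"`, `"d121"`.
#' @param ... passed to the family builder.
#' @return A `network_spec`.
#' @export
build_classifier <- function(arch = c("v7", "v16", "v19", "v21", "v24",
                                      "r34", "d121"), ...) {
  arch <- match.arg(arch)
  switch(arch,
    v7 = build_vgg(7L, ...), v16 = build_vgg(16L, ...),
    v19 = build_vgg(19L, ...), v21 = build_vgg(21L, ...),
    v24 = build_vgg(24L, ...),
    r34 = build_resnet34(...), d121 = build_densenet121(...))
}

#' Structural summary table of an architecture
#'
#' Flattens the architecture into one row per layer with kernel, stride,
#' padding and channel information, recursing through blocks.
#'
#' @param spec a `network_spec`.
#' @return A data.frame.
#' @export
layer_table <- function(spec) {
  rows <- list()
  walk <- function(layers, prefix = "") {
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      rows[[length(rows) + 1L]] <<- data.frame(
        where = paste0(prefix, i), type = ly$type,
        k = if (!is.null(ly$k)) ly$k else NA_integer_,
        stride = if (!is.null(ly$stride)) ly$stride else NA_integer_,
        pad = if (!is.null(ly$pad)) ly$pad else NA_integer_,
        out = if (!is.null(ly$out)) ly$out else NA_integer_,
        stringsAsFactors = FALSE)
      if (ly$type == "residual") walk(ly$layers, paste0(prefix, i, "."))
      if (ly$type == "dense_block") {
        rows[[length(rows)]]$out <<- ly$n_layers * ly$growth
      }
    }
  }
  walk(spec$layers)
  do.call(rbind, rows)
}
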