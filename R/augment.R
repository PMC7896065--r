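#' Augmentation specification
#'
#' Limits for the geometric augmentation of thoracic images. Translation
#' offsets are drawn as integers from `[0, limit]` with a random sign and a
#' random axis; rotation angles likewise from `[0, r_T]` degrees with a
#' random direction. The defaults (10 px horizontal, 4 px vertical, 5
#' degrees) reflect the patient displacement and tilt typically seen over a
#' long bone-scan acquisition.
#'
#' @param t_T_horizontal,t_T_vertical maximum translation in pixels.
#' @param r_T maximum rotation in degrees.
#' @param normalize apply per-image min-max normalization (the
#'   augmented-and-normalized dataset).
#' @param copies_per_image augmented copies generated per source image.
#' @param mirror_prob probability an augmented copy is mirrored.
#' @param rng_seed integer seed for all augmentation draws.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(t_T_horizontal = 10L, t_T_vertical = 4L, r_T = 5L,
                         normalize = FALSE, copies_per_image = 1L,
                         mirror_prob = 0.5, rng_seed = 1L) {
  if (t_T_horizontal < 0 || t_T_vertical < 0 || r_T < 0 || copies_per_image < 0) {
    stop("augment_spec: limits and copy counts must be nonnegative", call. = FALSE)
  }
  structure(list(t_T_horizontal = as.integer(t_T_horizontal),
                 t_T_vertical = as.integer(t_T_vertical),
                 r_T = as.integer(r_T), normalize = isTRUE(normalize),
                 copies_per_image = as.integer(copies_per_image),
                 mirror_prob = mirror_prob, rng_seed = as.integer(rng_seed)),
            class = "augment_spec")
}

aug_matrix <- function(img) {
  if (inherits(img, "thoracic_image")) img$dosage
  else if (inherits(img, "body_scan")) img$dosage
  else img
}

#' Horizontal mirror of a thoracic image
#'
#' Reverses the image right-to-left along its vertical centre line:
#' `out[i, j] = in[i, W + 1 - j]`. An involution; the dosage histogram is
#' preserved exactly.
#'
#' @param img matrix or `thoracic_image`.
#' @return A matrix of the same dimensions.
#' @export
mirror_image <- function(img) {
  m <- aug_matrix(img)
  m[, rev(seq_len(ncol(m))), drop = FALSE]
}

#' Translate a thoracic image by whole pixels
#'
#' Shifts content by `t` pixels along one axis; vacated pixels are set to 0
#' (background) and content shifted off the canvas is discarded. Positive
#' `t` moves content down (vertical) or right (horizontal).
#'
#' @param img matrix or `thoracic_image`.
#' @param t signed integer offset.
#' @param axis `"horizontal"` or `"vertical"`.
#' @param limit maximum `|t|` permitted (the augmentation bound for the
#'   axis); `Inf` disables the check.
#' @return A matrix of the same dimensions.
#' @export
translate_image <- function(img, t, axis = c("horizontal", "vertical"),
                            limit = Inf) {
  axis <- match.arg(axis)
  t <- as.integer(t)
  if (abs(t) > limit) {
    stop(sprintf("translate_image: |t| = %d exceeds the %s limit %s",
                 abs(t), axis, format(limit)), call. = FALSE)
  }
  m <- aug_matrix(img)
  out <- matrix(0L, nrow(m), ncol(m))
  if (axis == "horizontal") {
    src <- seq_len(ncol(m)) - t
    ok <- src >= 1L & src <= ncol(m)
    out[, which(ok)] <- m[, src[ok], drop = FALSE]
  } else {
    src <- seq_len(nrow(m)) - t
    ok <- src >= 1L & src <= nrow(m)
    out[which(ok), ] <- m[src[ok], , drop = FALSE]
  }
  storage.mode(out) <- storage.mode(m)
  out
}

#' Rotate a thoracic image about its geometric centre
#'
#' Rotates by `r` degrees (positive = clockwise in image coordinates)
#' about the canvas centre using inverse-mapping bilinear resampling on
#' the dosage values, rounded back to integers so 16-bit semantics are
#' kept. Content leaving the canvas is discarded; uncovered pixels are 0.
#' `r = 0` returns the input bit-exactly.
#'
#' @param img matrix or `thoracic_image`.
#' @param r signed rotation in degrees.
#' @param limit maximum `|r|` permitted; `Inf` disables the check.
#' @param round_int round the result back to integer dosage counts.
#' @return A matrix of the same dimensions.
#' @export
rotate_image <- function(img, r, limit = Inf, round_int = TRUE) {
  if (abs(r) > limit) {
    stop(sprintf("rotate_image: |r| = %s exceeds the limit %s",
                 format(abs(r)), format(limit)), call. = FALSE)
  }
  m <- aug_matrix(img)
  if (r == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- r * pi / 180
  # inverse map: for each output pixel, sample the input at the location
  # that rotates onto it
  out_r <- matrix(seq_len(H), H, W)
  out_c <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- out_r - cy; dx <- out_c - cx
  src_y <- cy + cos(th) * dy + sin(th) * dx
  src_x <- cx - sin(th) * dy + cos(th) * dx
  y0 <- floor(src_y); x0 <- floor(src_x)
  fy <- src_y - y0; fx <- src_x - x0
  pick <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- numeric(length(yy))
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fy) * (1 - fx) * pick(y0, x0) +
       (1 - fy) * fx       * pick(y0, x0 + 1) +
       fy       * (1 - fx) * pick(y0 + 1, x0) +
       fy       * fx       * pick(y0 + 1, x0 + 1)
  out <- matrix(v, H, W)
  if (round_int) {
    out <- matrix(as.integer(round(out)), H, W)
  }
  out
}

#' Per-image min-max normalization
#'
#' Affine rescaling of the dosage values to `[0, 1]`:
#' `(x - min) / (max - min)`. A constant image maps to all zeros. The map
#' is monotone, so pixel ordering is preserved.
#'
#' @param img matrix or `thoracic_image`.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
minmax_normalize <- function(img) {
  m <- aug_matrix(img)
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

# One random augmented copy: optional mirror, bounded random translation
# (random axis), bounded random rotation. Draws come from the current RNG
# stream; the caller seeds it.
random_augment <- function(m, spec) {
  ops <- character()
  if (runif(1) < spec$mirror_prob) {
    m <- mirror_image(m); ops <- c(ops, "mirror")
  }
  axis <- sample(c("horizontal", "vertical"), 1L)
  lim <- if (axis == "horizontal") spec$t_T_horizontal else spec$t_T_vertical
  t <- sample(0:lim, 1L) * sample(c(-1L, 1L), 1L)
  m <- translate_image(m, t, axis, limit = lim)
  ops <- c(ops, sprintf("translate(%s,%+d)", axis, t))
  r <- sample(0:spec$r_T, 1L) * sample(c(-1L, 1L), 1L)
  m <- rotate_image(m, r, limit = spec$r_T)
  ops <- c(ops, sprintf("rotate(%+d)", r))
  list(img = m, ops = paste(ops, collapse = ";"))
}

#' Assemble the original and augmented datasets
#'
#' Builds the three experimental datasets from cropped thoracic images:
#' `D1` are the originals; `D3` adds, per source image, random augmented
#' copies (mirror, bounded random translation, bounded random rotation);
#' `D2` is `D3` with per-image min-max normalization applied on top (the
#' geometric draws are shared between `D2` and `D3`). Class-specific copy
#' multipliers (or exact class targets) control the rebalancing, since
#' typically only part of the over-represented normal class is augmented.
#' Every augmented record carries provenance back to its source image, and
#' augmentation is label-preserving.
#'
#' @param images list of 256 x 256 dosage matrices (or `thoracic_image`s).
#' @param manifest data.frame with one row per image; must contain a
#'   `label` column, and optionally `scan_id` (defaults to the index).
#' @param spec an [augment_spec()]; `copies_per_image` is used when no
#'   class targets are given.
#' @param class_targets optional named vector of total record counts per
#'   label after augmentation, e.g. `c(normal = 1200, metastasis = 1190)`;
#'   extra copies are assigned round-robin over the class's source images.
#' @return A list with `D1`, `D2`, `D3`, each
#'   `list(images =, manifest =)`; manifests carry `source_id`, `ops`
#'   and `dataset` provenance columns.
#' @export
build_datasets <- function(images, manifest, spec = augment_spec(),
                           class_targets = NULL) {
  if (length(images) == 0L || nrow(manifest) == 0L) {
    stop("build_datasets: empty manifest", call. = FALSE)
  }
  if (length(images) != nrow(manifest)) {
    stop("build_datasets: images and manifest lengths differ", call. = FALSE)
  }
  if (is.null(manifest$scan_id)) manifest$scan_id <- sprintf("img%04d", seq_len(nrow(manifest)))
  base <- data.frame(record_id = manifest$scan_id,
                     source_id = manifest$scan_id,
                     label = manifest$label,
                     ops = "original",
                     stringsAsFactors = FALSE)

  # per-source copy counts
  n <- nrow(manifest)
  copies <- rep(spec$copies_per_image, n)
  if (!is.null(class_targets)) {
    copies <- integer(n)
    for (lab in names(class_targets)) {
      idx <- which(manifest$label == lab)
      extra <- class_targets[[lab]] - length(idx)
      if (extra < 0) {
        stop("build_datasets: class target below the original count for '",
             lab, "'", call. = FALSE)
      }
      if (length(idx) > 0L && extra > 0L) {
        copies[idx] <- extra %/% length(idx) +
          (seq_along(idx) <= extra %% length(idx))
      }
    }
  }

  set.seed(spec$rng_seed)
  aug_images <- list(); aug_rows <- list()
  for (i in seq_len(n)) {
    m <- aug_matrix(images[[i]])
    for (k in seq_len(copies[i])) {
      a <- random_augment(m, spec)
      aug_images[[length(aug_images) + 1L]] <- a$img
      aug_rows[[length(aug_rows) + 1L]] <- data.frame(
        record_id = sprintf("%s_aug%02d", manifest$scan_id[i], k),
        source_id = manifest$scan_id[i],
        label = manifest$label[i],
        ops = a$ops, stringsAsFactors = FALSE)
    }
  }
  orig_images <- lapply(images, aug_matrix)
  d3_images <- c(orig_images, aug_images)
  d3_manifest <- rbind(base, if (length(aug_rows)) do.call(rbind, aug_rows))
  d2_images <- lapply(d3_images, minmax_normalize)

  list(
    D1 = list(images = orig_images,
              manifest = transform(base, dataset = "D1")),
    D2 = list(images = d2_images,
              manifest = transform(d3_manifest, dataset = "D2")),
    D3 = list(images = d3_images,
              manifest = transform(d3_manifest, dataset = "D3"))
  )
}

#' Block-mean downscaling of a square image
#'
#' Reduces a `(k*s) x (k*s)` dosage matrix to `s x s` by averaging `k x k`
#' blocks (used to run scaled-down training experiments on cropped
#' thoracic images).
#'
#' @param img matrix or `thoracic_image`.
#' @param size output side length; must divide evenly into the input side.
#' @return A numeric `size x size` matrix.
#' @export
downscale_image <- function(img, size = 64L) {
  m <- aug_matrix(img)
  k <- nrow(m) / size
  if (k != as.integer(k) || ncol(m) != nrow(m)) {
    stop("downscale_image: input must be square and divisible by size", call. = FALSE)
  }
  k <- as.integer(k)
  # average over k x k blocks via index arithmetic
  ridx <- rep(seq_len(size), each = k)
  t1 <- rowsum(m, ridx, reorder = TRUE)
  t2 <- rowsum(t(t1), ridx, reorder = TRUE)
  t(t2) / (k * k)
}
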