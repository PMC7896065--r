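#' Parameters of the thoracic cropping pipeline
#'
#' @param sigma penalty factor in pixels, the symmetric expansion applied
#'   to the crop bounds to absorb curve-fitting error. Drawn uniformly
#'   from the open interval (5, 15) when `NULL`.
#' @param smoothing_window width in rows of the centred moving average
#'   used as the fitted curve over the raw row counts.
#' @param peak_prominence_frac minimum prominence of a peak/valley as a
#'   fraction of the fitted-curve maximum; suppresses noise extrema.
#' @param spine_pelvis_ratio length-2 spine : pelvis height ratio used to
#'   split the trunk-plus-pelvis span (default `c(3, 2)`).
#' @param profile_stat `"count"` counts nonzero pixels per row (default);
#'   `"sum"` sums dosage per row instead.
#' @param out_size side of the square output canvas in pixels.
#' @param rng_seed seed driving the sigma draw.
#' @return A `crop_params` list.
#' @export
crop_params <- function(sigma = NULL,
                        smoothing_window = 15L,
                        peak_prominence_frac = 0.05,
                        spine_pelvis_ratio = c(3, 2),
                        profile_stat = c("count", "sum"),
                        out_size = 256L,
                        rng_seed = 1L) {
  profile_stat <- match.arg(profile_stat)
  if (!is.null(sigma) && (sigma <= 5 || sigma >= 15)) {
    stop("crop_params: sigma must lie in the open interval (5, 15)", call. = FALSE)
  }
  structure(list(sigma = sigma, smoothing_window = as.integer(smoothing_window),
                 peak_prominence_frac = peak_prominence_frac,
                 spine_pelvis_ratio = spine_pelvis_ratio,
                 profile_stat = profile_stat, out_size = as.integer(out_size),
                 rng_seed = as.integer(rng_seed)),
            class = "crop_params")
}

#' Stage 1: adaptive noise threshold
#'
#' The threshold of noise is the maximum radiation dosage outside the body
#' area. When the outside region is not supplied, it is estimated
#' deterministically by a coarse Otsu split of the dosage values followed
#' by a border-connected component sweep: pixels below the split that are
#' connected to the image border form the outside region.
#'
#' @param scan a [body_scan()] or dosage matrix.
#' @param outside_hint optional logical matrix marking outside-body pixels
#'   (e.g. the complement of a phantom's body mask); when given it is used
#'   directly.
#' @return `thr_N`, the maximum dosage over the (estimated) outside
#'   region; 0 for an all-zero image.
#' @export
noise_threshold <- function(scan, outside_hint = NULL) {
  x <- as_scan(scan)$dosage
  if (max(x) == 0L) return(0L)
  if (!is.null(outside_hint)) {
    if (!any(outside_hint)) return(0L)
    return(max(x[outside_hint]))
  }
  split <- EBImage::otsu(EBImage::Image(x / 65535), range = c(0, 1),
                         levels = 65536L) * 65535
  low <- EBImage::Image(x < split)
  comp <- EBImage::bwlabel(low)
  cm <- EBImage::imageData(comp)
  border_labels <- setdiff(unique(c(cm[1, ], cm[nrow(cm), ], cm[, 1],
                                    cm[, ncol(cm)])), 0)
  if (length(border_labels) == 0L) return(0L)
  outside <- matrix(cm %in% border_labels, nrow(x), ncol(x))
  # keep a safety margin: the faint taper at the body edge must not be
  # mistaken for background, so exclude a dilated halo of the above-split
  # region from the outside estimate
  halo <- EBImage::dilate(EBImage::Image((x >= split) * 1),
                          EBImage::makeBrush(9L, "diamond"))
  outside <- outside & !(EBImage::imageData(halo) > 0)
  if (!any(outside)) return(0L)
  max(x[outside])
}

#' Stage 1: strip background below the noise threshold
#'
#' Pixels with dosage strictly less than `thr_N` are set to 0; all others
#' are unchanged. Idempotent. The full pipeline applies the measured
#' threshold inclusively (see [crop_pipeline()]).
#'
#' @param scan a [body_scan()] or dosage matrix.
#' @param thr_N nonnegative threshold.
#' @return A [body_scan()] with the background zeroed.
#' @export
strip_background <- function(scan, thr_N) {
  scan <- as_scan(scan)
  if (thr_N < 0) stop("strip_background: thr_N must be >= 0", call. = FALSE)
  d <- scan$dosage
  d[d < thr_N] <- 0L
  body_scan(d, view = scan$view, patient_id = scan$patient_id)
}

#' Stage 2: vertical extent of the body
#'
#' @param scan a denoised [body_scan()] or matrix.
#' @return `c(top_row, bottom_row)`: the first and last rows containing a
#'   nonzero pixel.
#' @export
body_extent <- function(scan) {
  d <- as_scan(scan)$dosage
  nz <- which(rowSums(d > 0L) > 0L)
  if (length(nz) == 0L) {
    stop("body_extent: empty body (image has no nonzero pixel)", call. = FALSE)
  }
  c(top_row = nz[1], bottom_row = nz[length(nz)])
}

# Centred moving average with edge-shrinking windows (the ends of the
# profile are averaged over the in-range part of the window).
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  k <- rep(1, window)
  num <- stats::filter(x, k, sides = 2)
  den <- stats::filter(rep(1, length(x)), k, sides = 2)
  half <- window %/% 2L
  n <- length(x)
  out <- as.numeric(num / den)
  for (i in which(is.na(out))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Stage 3: per-row profile of the denoised body
#'
#' Counts nonzero pixels per row (or sums dosage, see [crop_params()])
#' within the body extent, smooths the counts with a centred moving
#' average (the "fitted curve"), and takes first and second derivatives by
#' central finite differences.
#'
#' @param scan denoised [body_scan()] or matrix.
#' @param extent `c(top_row, bottom_row)` from [body_extent()].
#' @param smoothing_window rows in the moving-average window.
#' @param stat `"count"` or `"sum"`.
#' @return A `row_profile` list: `rows` (absolute row indices), `counts`,
#'   `fitted`, `d1`, `d2`.
#' @export
row_profile <- function(scan, extent = body_extent(scan),
                        smoothing_window = 15L, stat = c("count", "sum")) {
  stat <- match.arg(stat)
  d <- as_scan(scan)$dosage
  rows <- seq.int(extent[1], extent[2])
  counts <- if (stat == "count") rowSums(d[rows, , drop = FALSE] > 0L)
            else rowSums(d[rows, , drop = FALSE])
  fitted <- moving_average(counts, smoothing_window)
  n <- length(fitted)
  d1 <- numeric(n); d2 <- numeric(n)
  if (n >= 3L) {
    i <- 2:(n - 1)
    d1[i] <- (fitted[i + 1] - fitted[i - 1]) / 2
    d2[i] <- fitted[i + 1] - 2 * fitted[i] + fitted[i - 1]
    d1[1] <- fitted[2] - fitted[1]; d1[n] <- fitted[n] - fitted[n - 1]
    d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  }
  structure(list(rows = rows, counts = as.numeric(counts),
                 fitted = fitted, d1 = d1, d2 = d2,
                 smoothing_window = as.integer(smoothing_window)),
            class = "row_profile")
}

# Local extrema of a curve by sign changes of its first difference, with a
# standard prominence filter: the prominence of a peak is its height above
# the higher of the two lowest points separating it from higher terrain.
find_extrema <- function(y, min_prominence) {
  n <- length(y)
  if (n < 3L) return(list(peaks = integer(), valleys = integer()))
  dy <- diff(y)
  s <- sign(dy)
  # carry the sign over flat stretches so plateaus count once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) != 0) + 1L
  cand_peaks <- idx[s[idx - 1L] > 0]
  cand_valleys <- idx[s[idx - 1L] < 0]
  prominence <- function(i) {
    left <- y[seq_len(i)]; right <- y[i:n]
    higher_l <- which(left > y[i]); higher_r <- which(right > y[i]) + i - 1L
    lo_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    lo_r <- if (length(higher_r)) min(y[i:min(higher_r)]) else min(right)
    y[i] - max(lo_l, lo_r)
  }
  peaks <- cand_peaks[vapply(cand_peaks, prominence, numeric(1)) >= min_prominence]
  yv <- -y
  prominence_v <- function(i) {
    left <- yv[seq_len(i)]; right <- yv[i:n]
    higher_l <- which(left > yv[i]); higher_r <- which(right > yv[i]) + i - 1L
    lo_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    lo_r <- if (length(higher_r)) min(yv[i:min(higher_r)]) else min(right)
    yv[i] - max(lo_l, lo_r)
  }
  valleys <- cand_valleys[vapply(cand_valleys, prominence_v, numeric(1)) >= min_prominence]
  list(peaks = peaks, valleys = valleys)
}

#' Stage 3: landmark rows from a row profile
#'
#' The first three peaks of the fitted curve, read top-down, mark the
#' head, the elbow and the shoulder; the third valley marks the onset of
#' the legs. Peaks and valleys are located by sign changes of the first
#' derivative and filtered by a minimum prominence (a fraction of the
#' fitted maximum).
#'
#' @param profile a [row_profile()].
#' @param peak_prominence_frac minimum prominence as a fraction of
#'   `max(fitted)`.
#' @return A `landmarks` list: `head_peak`, `elbow_peak`, `shoulder_peak`,
#'   `leg_valley` (absolute row indices). On failure, throws a condition of
#'   class `landmark_error` carrying the partial result in `$partial`.
#' @export
landmark_rows <- function(profile, peak_prominence_frac = 0.05) {
  stopifnot(inherits(profile, "row_profile"))
  y <- profile$fitted
  ext <- find_extrema(y, peak_prominence_frac * max(y))
  partial <- list(peaks = profile$rows[ext$peaks],
                  valleys = profile$rows[ext$valleys])
  if (length(ext$peaks) < 3L || length(ext$valleys) < 3L) {
    cond <- structure(class = c("landmark_error", "error", "condition"),
                      list(message = sprintf(
                        "landmark detection: found %d peaks and %d valleys, need 3 of each",
                        length(ext$peaks), length(ext$valleys)),
                        call = NULL, partial = partial))
    stop(cond)
  }
  structure(list(head_peak = profile$rows[ext$peaks[1]],
                 elbow_peak = profile$rows[ext$peaks[2]],
                 shoulder_peak = profile$rows[ext$peaks[3]],
                 leg_valley = profile$rows[ext$valleys[3]],
                 all_peaks = partial$peaks, all_valleys = partial$valleys),
            class = "landmarks")
}

#' Stage 4: thoracic crop bounds
#'
#' The thorax top is the shoulder peak. The trunk-plus-pelvis span down to
#' the leg valley is divided so that spine : pelvis heights are 3 : 2,
#' placing the thorax bottom at `row0 + round(3/5 * (leg_valley - row0))`.
#' Columns are the horizontal extent of nonzero pixels over the thorax
#' rows; where the arms inflate that extent beyond the width of the leg
#' area (whose width matches the trunk), the extent is shrunk
#' symmetrically to the leg-area width, tie-breaking toward the wider
#' crop.
#'
#' @param landmarks a [landmark_rows()] result.
#' @param profile the [row_profile()] (used for the leg-area rows).
#' @param scan the denoised [body_scan()].
#' @param spine_pelvis_ratio length-2 ratio, default `c(3, 2)`.
#' @return A `crop_bounds` list: `row0`, `row1`, `col0`, `col1`
#'   (inclusive), before penalty expansion.
#' @export
thorax_bounds <- function(landmarks, profile, scan,
                          spine_pelvis_ratio = c(3, 2)) {
  d <- as_scan(scan)$dosage
  row0 <- landmarks$shoulder_peak
  span <- landmarks$leg_valley - row0
  if (span <= 0) {
    stop("thorax_bounds: degenerate span (leg valley at or above the shoulder peak)",
         call. = FALSE)
  }
  frac <- spine_pelvis_ratio[1] / sum(spine_pelvis_ratio)
  row1 <- row0 + as.integer(round(frac * span))
  if (row1 <= row0) {
    stop("thorax_bounds: degenerate bounds (row1 <= row0)", call. = FALSE)
  }

  col_extent <- function(rows) {
    rows <- rows[rows >= 1 & rows <= nrow(d)]
    nz <- which(colSums(d[rows, , drop = FALSE] > 0L) > 0L)
    if (length(nz) == 0L) return(NULL)
    c(nz[1], nz[length(nz)])
  }
  trunk <- col_extent(row0:row1)
  if (is.null(trunk)) {
    stop("thorax_bounds: no nonzero pixels in the thorax rows", call. = FALSE)
  }
  legs <- col_extent((landmarks$leg_valley + 5L):(landmarks$leg_valley + 30L))
  col0 <- trunk[1]; col1 <- trunk[2]
  if (!is.null(legs)) {
    leg_width <- legs[2] - legs[1] + 1L
    trunk_width <- col1 - col0 + 1L
    if (trunk_width > leg_width) {  # arms inflate the trunk extent: cap it
      centre <- (col0 + col1) / 2
      col0 <- as.integer(floor(centre - leg_width / 2 + 0.5))
      col1 <- col0 + leg_width - 1L
      col0 <- max(1L, col0); col1 <- min(ncol(d), col1)
    }
  }
  structure(list(row0 = as.integer(row0), row1 = as.integer(row1),
                 col0 = as.integer(col0), col1 = as.integer(col1)),
            class = "crop_bounds")
}

#' Stage 5: crop, pad with background, centre on a square canvas
#'
#' The bounds are expanded by the penalty factor `sigma` on every side
#' (clamped to the image), the block is cut out with dosage values
#' unchanged, and placed centred on an `out_size` x `out_size` canvas of
#' zeros (background). A crop larger than the canvas in either dimension
#' is trimmed symmetrically to fit, with a warning.
#'
#' @param scan the [body_scan()] to crop (typically the denoised one).
#' @param bounds a [thorax_bounds()] result.
#' @param sigma penalty factor in pixels, in the open interval (5, 15).
#' @param out_size output canvas side (default 256).
#' @return A `thoracic_image` list: `dosage` (out_size x out_size integer
#'   matrix), `bounds`, `expanded_bounds`, `sigma`, `offset` (placement of
#'   the block on the canvas).
#' @export
crop_thorax <- function(scan, bounds, sigma, out_size = 256L) {
  d <- as_scan(scan)$dosage
  if (sigma <= 5 || sigma >= 15) {
    stop("crop_thorax: sigma must lie in the open interval (5, 15)", call. = FALSE)
  }
  s <- as.integer(round(sigma))
  r0 <- max(1L, bounds$row0 - s); r1 <- min(nrow(d), bounds$row1 + s)
  c0 <- max(1L, bounds$col0 - s); c1 <- min(ncol(d), bounds$col1 + s)
  if (r1 - r0 + 1L > out_size) {
    warning("crop_thorax: expanded crop height exceeds ", out_size,
            "; trimming symmetrically", call. = FALSE)
    excess <- (r1 - r0 + 1L) - out_size
    r0 <- r0 + excess %/% 2L; r1 <- r0 + out_size - 1L
  }
  if (c1 - c0 + 1L > out_size) {
    warning("crop_thorax: expanded crop width exceeds ", out_size,
            "; trimming symmetrically", call. = FALSE)
    excess <- (c1 - c0 + 1L) - out_size
    c0 <- c0 + excess %/% 2L; c1 <- c0 + out_size - 1L
  }
  block <- d[r0:r1, c0:c1, drop = FALSE]
  canvas <- matrix(0L, out_size, out_size)
  off_r <- (out_size - nrow(block)) %/% 2L
  off_c <- (out_size - ncol(block)) %/% 2L
  canvas[off_r + seq_len(nrow(block)), off_c + seq_len(ncol(block))] <- block
  structure(list(dosage = canvas, bounds = bounds,
                 expanded_bounds = list(row0 = r0, row1 = r1, col0 = c0, col1 = c1),
                 sigma = sigma, offset = c(row = off_r, col = off_c)),
            class = "thoracic_image")
}

#' @export
print.thoracic_image <- function(x, ...) {
  cat(sprintf("<thoracic_image> %d x %d, sigma=%.2f, source rows %d..%d cols %d..%d\n",
              nrow(x$dosage), ncol(x$dosage), x$sigma,
              x$expanded_bounds$row0, x$expanded_bounds$row1,
              x$expanded_bounds$col0, x$expanded_bounds$col1))
  invisible(x)
}

# Map a source-image pixel set into crop-canvas coordinates; drops pixels
# that fall outside the canvas.
map_to_crop <- function(pixels, thoracic) {
  eb <- thoracic$expanded_bounds
  r <- pixels[, 1] - eb$row0 + 1L + thoracic$offset["row"]
  c <- pixels[, 2] - eb$col0 + 1L + thoracic$offset["col"]
  keep <- pixels[, 1] >= eb$row0 & pixels[, 1] <= eb$row1 &
          pixels[, 2] >= eb$col0 & pixels[, 2] <= eb$col1
  cbind(row = r[keep], col = c[keep])
}

#' Full five-stage thoracic cropping pipeline
#'
#' Runs, in order: adaptive noise thresholding (the measured outside-body
#' maximum is applied inclusively, so every pixel at or below it is
#' background), body-extent extraction, row profiling with landmark
#' detection, the 3:2 spine-to-pelvis bound computation, and the
#' penalty-expanded crop onto a 256 x 256 canvas. Errors from any stage
#' are rethrown with the stage name attached. Deterministic given
#' `(scan, params$rng_seed)`.
#'
#' @param scan a [body_scan()] or dosage matrix.
#' @param params a [crop_params()].
#' @param outside_hint optional outside-body mask for Stage 1.
#' @return A list: `thoracic` ([crop_thorax()] result), `bounds`,
#'   `landmarks`, `profile`, `thr_N`, `sigma`.
#' @export
crop_pipeline <- function(scan, params = crop_params(), outside_hint = NULL) {
  scan <- as_scan(scan)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      e$message <- paste0("[", name, "] ", conditionMessage(e))
      stop(e)
    })
  }
  thr <- stage("stage1-threshold", noise_threshold(scan, outside_hint))
  clean <- stage("stage1-strip", strip_background(scan, thr + 1L))
  extent <- stage("stage2-extent", body_extent(clean))
  profile <- stage("stage3-profile",
                   row_profile(clean, extent, params$smoothing_window,
                               params$profile_stat))
  lms <- stage("stage3-landmarks",
               landmark_rows(profile, params$peak_prominence_frac))
  bounds <- stage("stage4-bounds",
                  thorax_bounds(lms, profile, clean, params$spine_pelvis_ratio))
  sigma <- params$sigma
  if (is.null(sigma)) {
    set.seed(params$rng_seed)
    sigma <- runif(1, 5, 15)
    while (sigma <= 5 || sigma >= 15) sigma <- runif(1, 5, 15)
  }
  thoracic <- stage("stage5-crop",
                    crop_thorax(clean, bounds, sigma, params$out_size))
  list(thoracic = thoracic, bounds = bounds, landmarks = lms,
       profile = profile, thr_N = thr, sigma = sigma)
}

#' Intersection-over-union of two inclusive pixel boxes
#'
#' @param a,b boxes as `(row0, row1, col0, col1)` (lists or vectors,
#'   inclusive bounds).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- unlist(a)[1:4]; b <- unlist(b)[1:4]
  ir <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  ic <- max(0, min(a[4], b[4]) - max(a[3], b[3]) + 1)
  inter <- ir * ic
  area <- function(x) (x[2] - x[1] + 1) * (x[4] - x[3] + 1)
  un <- area(a) + area(b) - inter
  if (un <= 0) return(0)
  unname(inter / un)
}
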