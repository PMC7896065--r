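#' Parameters for the synthetic whole-body scan generator
#'
#' Bundles every knob of the phantom generator. Dosage parameters are in
#' raw radiation-dosage counts (16-bit unsigned range, 0..65535). Defaults
#' are chosen so that the 16-bit range is exercised the way clinical bone
#' scans exercise it: a soft-tissue/bone body signal around 500--2000
#' counts, focal hot spots around 3000--6000, sparse background noise well
#' below the body signal, and very hot non-lesion confounders (tracer
#' injection point on an arm, bladder pooling in the pelvis).
#'
#' @param image_width,image_height canvas size in pixels (default 256 x 1024).
#' @param background_noise_max maximum background (outside-body) noise
#'   count; noise is drawn i.i.d. uniform on `0..background_noise_max`.
#'   Must be strictly below `body_base_dosage` so body and background are
#'   separable by thresholding.
#' @param body_base_dosage mean dosage of body tissue at full depth.
#' @param hotspot_dosage_range length-2 `(low, high)`: every lesion pixel
#'   is guaranteed `>= low`; lesion mean dosage is drawn in `[low, high]`.
#' @param lesion_count_range length-2 integer `(min, max)` number of
#'   lesions; `(0, 0)` forces a normal scan.
#' @param injection_point,bladder logical; include the high-uptake
#'   confounders.
#' @param view `"anterior"` or `"posterior"`. The posterior view mirrors
#'   the anterior silhouette left-to-right and redraws noise.
#' @param subcategory lesion placement pattern: `"none"` (normal),
#'   `"spinal"` (one spine lesion), `"multiple"` (several spine/rib
#'   lesions), `"outside_spinal"` (one lesion outside the thorax, e.g.
#'   pelvis), or `NULL` to infer from the drawn lesion count.
#' @param rng_seed integer seed for geometry and lesion draws.
#' @param noise_seed integer seed for noise and count jitter; defaults to
#'   `rng_seed + 1L` for the anterior view and `rng_seed + 2L` for the
#'   posterior view, so paired views share anatomy but not noise.
#'
#' @return An object of class `phantom_params` (a validated list).
#' @export
phantom_params <- function(image_width = 256L,
                           image_height = 1024L,
                           background_noise_max = 50L,
                           body_base_dosage = 800L,
                           hotspot_dosage_range = c(3000L, 6000L),
                           lesion_count_range = c(1L, 4L),
                           injection_point = TRUE,
                           bladder = TRUE,
                           view = c("anterior", "posterior"),
                           subcategory = NULL,
                           rng_seed = 1L,
                           noise_seed = NULL) {
  view <- match.arg(view)
  if (is.null(noise_seed)) {
    noise_seed <- rng_seed + if (view == "anterior") 1L else 2L
  }
  p <- list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    background_noise_max = as.integer(background_noise_max),
    body_base_dosage = as.integer(body_base_dosage),
    hotspot_dosage_range = as.integer(hotspot_dosage_range),
    lesion_count_range = as.integer(lesion_count_range),
    injection_point = isTRUE(injection_point),
    bladder = isTRUE(bladder),
    view = view,
    subcategory = subcategory,
    rng_seed = as.integer(rng_seed),
    noise_seed = as.integer(noise_seed)
  )
  validate_phantom_params(p)
  class(p) <- "phantom_params"
  p
}

validate_phantom_params <- function(p) {
  if (p$image_width < 64L || p$image_height < 256L) {
    stop("phantom: image dimensions too small (need width >= 64, height >= 256)",
         call. = FALSE)
  }
  dos <- c(p$background_noise_max, p$body_base_dosage, p$hotspot_dosage_range)
  if (any(dos < 0L) || any(dos > 65535L)) {
    stop("phantom: dosage parameters must lie in [0, 65535] (16-bit unsigned)",
         call. = FALSE)
  }
  if (p$background_noise_max >= p$body_base_dosage) {
    stop("phantom: background_noise_max must be < body_base_dosage ",
         "(noise must be separable by thresholding)", call. = FALSE)
  }
  if (length(p$lesion_count_range) != 2L || any(p$lesion_count_range < 0L) ||
      p$lesion_count_range[1] > p$lesion_count_range[2]) {
    stop("phantom: lesion_count_range must be nondecreasing and nonnegative",
         call. = FALSE)
  }
  if (length(p$hotspot_dosage_range) != 2L ||
      p$hotspot_dosage_range[1] > p$hotspot_dosage_range[2]) {
    stop("phantom: hotspot_dosage_range must be (low, high) with low <= high",
         call. = FALSE)
  }
  if (!is.null(p$subcategory) &&
      !p$subcategory %in% c("none", "spinal", "multiple", "outside_spinal")) {
    stop("phantom: unknown subcategory '", p$subcategory, "'", call. = FALSE)
  }
  invisible(p)
}

# Piecewise-linear interpolation of (row, value) key points over all rows.
pw <- function(keys, rows) {
  stats::approx(x = keys[, 1], y = keys[, 2], xout = rows, rule = 2)$y
}

# Draw the silhouette geometry for one simulated patient (anterior frame).
# All row anchors and half-widths; jittered around a reference anatomy so
# that the per-row nonzero-count profile has the canonical whole-body
# structure: three leading peaks (head, then the two upper-trunk peaks
# conventionally read as elbow and shoulder) and a third valley at the
# onset of the legs.
phantom_geometry <- function(p) {
  H <- p$image_height
  sc <- H / 1024                              # row scale for non-default heights
  j <- function(k) sample(seq(-k, k), 1L)     # symmetric integer jitter
  vshift <- j(12L)
  ws <- runif(1, 0.92, 1.08)                  # global width scale
  centre <- round(p$image_width / 2) + j(5L)

  r <- function(x) as.integer(round(x * sc)) + vshift
  head_top  <- r(40) + j(4L)
  head_peak <- r(80) + j(4L)
  head_end  <- r(118)
  neck_end  <- r(136)
  elbow_peak    <- r(152) + j(4L)   # 2nd profile peak (shoulder-tip flare)
  axilla        <- r(168)           # dip where the arms separate
  shoulder_peak <- r(192) + j(4L)   # 3rd profile peak = top of the thorax
  trunk_start   <- shoulder_peak + r(7) - vshift
  arm_end    <- r(392) + j(6L)
  pelvis_end <- r(520)
  leg_valley <- r(558) + j(6L)
  thigh      <- leg_valley + (r(20) - vshift)
  knees      <- r(650)
  feet_end   <- r(952) + j(5L)

  w <- function(x) ws * x * min(1, p$image_width / 256)
  hw_keys <- rbind(  # central-band half-width (head/neck/trunk/pelvis/legs outer)
    c(head_top,  w(2)),
    c(head_top + (head_peak - head_top) / 2, w(26)),
    c(head_peak, w(32)),
    c(head_end,  w(16)),
    c(neck_end,  w(15)),
    c(elbow_peak, w(74)),
    c(axilla,     w(60)),
    c(shoulder_peak, w(56)),
    c(trunk_start,   w(55)),
    c(arm_end,    w(51)),
    c(pelvis_end, w(50)),
    c(leg_valley, w(49)),
    c(thigh,      w(56)),
    c(knees,      w(56)),
    c(feet_end,   w(45))
  )
  gap_keys <- rbind( # central gap half-width (crotch and between the legs)
    c(pelvis_end, 0),
    c(leg_valley, w(17.5)),
    c(thigh,      w(15)),
    c(knees,      w(15)),
    c(feet_end,   w(21))
  )
  arm_keys <- rbind( # arm-band width; arms sit 6 px outside the trunk edge
    c(axilla,      0),
    c(shoulder_peak, w(18)),
    c(trunk_start,   w(17)),
    c(arm_end - r(10) + vshift, w(10)),
    c(arm_end,     0)
  )

  trunk_hw <- max(hw_keys[hw_keys[, 1] >= shoulder_peak &
                          hw_keys[, 1] <= pelvis_end, 2])
  thorax_row0 <- shoulder_peak
  thorax_row1 <- shoulder_peak + round(3 / 5 * (leg_valley - shoulder_peak))

  list(
    centre = centre, width_scale = ws,
    head_top = head_top, head_peak = head_peak, head_end = head_end,
    neck_end = neck_end, elbow_peak = elbow_peak, axilla = axilla,
    shoulder_peak = shoulder_peak, trunk_start = trunk_start,
    arm_end = arm_end, pelvis_end = pelvis_end, leg_valley = leg_valley,
    thigh = thigh, feet_end = feet_end,
    hw_keys = hw_keys, gap_keys = gap_keys, arm_keys = arm_keys,
    arm_gap = 6 * ws,
    thorax_box = c(row0 = thorax_row0, row1 = thorax_row1,
                   col0 = as.integer(round(centre - trunk_hw)),
                   col1 = as.integer(round(centre + trunk_hw))),
    body_row_range = c(top = head_top, bottom = feet_end)
  )
}

# Per-row band edges (vectors over 1..H) from a geometry.
phantom_bands <- function(geom, H) {
  rows <- seq_len(H)
  hw  <- pw(geom$hw_keys,  rows)
  gap <- pw(geom$gap_keys, rows)
  gap[rows < geom$pelvis_end] <- 0
  arm_w <- pw(geom$arm_keys, rows)
  arm_w[rows < geom$axilla | rows > geom$arm_end] <- 0
  hw[rows < geom$head_top | rows > geom$feet_end] <- -1
  list(hw = hw, gap = gap, arm_w = arm_w)
}

# Logical body mask (H x W) from band edges.
phantom_mask <- function(geom, H, W) {
  b <- phantom_bands(geom, H)
  D <- abs(matrix(seq_len(W), H, W, byrow = TRUE) - geom$centre)
  HW <- matrix(b$hw, H, W)
  G  <- matrix(b$gap, H, W)
  central <- D <= HW & D >= G
  AIN  <- HW + geom$arm_gap
  AOUT <- AIN + matrix(b$arm_w, H, W)
  arms <- b$arm_w > 0
  arm_band <- D >= AIN & D <= AOUT & matrix(arms, H, W)
  list(body = central | arm_band, central = central, arms = arm_band,
       D = D, HW = HW, G = G)
}

# Draw lesion discs for a given subcategory; returns list of (row, col)
# matrices. Lesions are kept inside the spine/rib area of the thorax box
# (spinal/multiple) or in the pelvis (outside_spinal).
phantom_lesions <- function(geom, p) {
  sub <- p$subcategory
  lo <- p$lesion_count_range[1]; hi <- p$lesion_count_range[2]
  n <- if (lo == hi) lo else sample(lo:hi, 1L)
  if (is.null(sub)) {
    sub <- if (n == 0L) "none" else if (n == 1L) "spinal" else "multiple"
  }
  if (sub == "none") return(list(sub = "none", masks = list()))
  if (sub %in% c("spinal", "outside_spinal")) n <- max(1L, min(n, 1L))
  if (sub == "multiple") n <- max(2L, n)

  tb <- geom$thorax_box
  ws <- geom$width_scale
  masks <- vector("list", n)
  for (k in seq_len(n)) {
    rad <- sample(3:6, 1L)
    if (sub == "outside_spinal") {
      # pelvis proper: below the thorax box but above the crotch gap
      rr <- sample(seq(tb["row1"] + 15L, geom$pelvis_end - 20L), 1L)
      cc <- geom$centre + sample(-12:12, 1L)
    } else if (sub == "spinal" || k == 1L) {
      rr <- sample(seq(tb["row0"] + 15L, tb["row1"] - 10L), 1L)
      cc <- geom$centre + sample(-8:8, 1L)
    } else { # additional lesions of a "multiple" scan: ribs or spine
      rr <- sample(seq(tb["row0"] + 12L, tb["row1"] - 8L), 1L)
      off <- sample(c(-1, 1), 1L) * sample(seq(18L, round(40 * ws)), 1L)
      cc <- geom$centre + off
    }
    grid <- expand.grid(row = (rr - rad):(rr + rad), col = (cc - rad):(cc + rad))
    keep <- (grid$row - rr)^2 + (grid$col - cc)^2 <= rad^2
    masks[[k]] <- as.matrix(grid[keep, , drop = FALSE])
  }
  list(sub = sub, masks = masks)
}

#' Generate one synthetic whole-body bone scan with ground truth
#'
#' Builds a body silhouette from piecewise geometric primitives (head,
#' neck, shoulder and elbow flares, trunk with separate arm bands, pelvis,
#' legs) whose per-row nonzero-pixel count exhibits the canonical
#' whole-body profile: three leading peaks and a valley at the onset of
#' the legs. Body dosage is Poisson-distributed around a depth-weighted
#' base with a hotter spine band and a periodic rib texture; background
#' pixels carry independent uniform integer noise on
#' `0..background_noise_max`. Optional metastatic hot spots and the
#' injection-point / bladder confounders are painted on top.
#'
#' Identical `params` (including seeds) give a bit-identical scan and
#' ground truth. The posterior view mirrors the anterior silhouette
#' left-to-right and redraws the stochastic components.
#'
#' @param params a [phantom_params()] object.
#' @return A list with components
#'   \describe{
#'     \item{scan}{a `body_scan` (see [body_scan()]) of dosage counts.}
#'     \item{truth}{a `phantom_truth` list: `body_row_range`,
#'       `thorax_box`, `landmark_rows` (`head_peak`, `elbow_peak`,
#'       `shoulder_peak`, `leg_valley`), `lesion_masks` (list of
#'       `(row, col)` matrices), `body_mask` (logical matrix; the
#'       outside-body mask is its complement), `label`
#'       (`"normal"`/`"metastasis"`) and `subcategory`.}
#'   }
#' @examples
#' sc <- generate_scan(phantom_params(rng_seed = 7))
#' dim(sc$scan$dosage)
#' sc$truth$label
#' @export
generate_scan <- function(params) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  validate_phantom_params(params)
  H <- params$image_height; W <- params$image_width

  set.seed(params$rng_seed)
  geom <- phantom_geometry(params)
  les <- phantom_lesions(geom, params)

  if (params$view == "posterior") {
    # mirror the silhouette about the vertical centre line
    geom$centre <- W + 1L - geom$centre
    les$masks <- lapply(les$masks, function(m) {
      m[, "col"] <- W + 1L - m[, "col"]; m
    })
    geom$thorax_box[c("col0", "col1")] <-
      sort(W + 1L - geom$thorax_box[c("col1", "col0")])
  }

  mk <- phantom_mask(geom, H, W)
  body <- mk$body
  # lesions live in bone, i.e. inside the body: clip masks to the silhouette
  les$masks <- Filter(function(m) nrow(m) > 0L,
                      lapply(les$masks, function(m) m[body[m], , drop = FALSE]))

  # deterministic mean-dosage field
  base <- params$body_base_dosage
  depth_central <- ifelse(mk$G > 0,
    sqrt(pmax(0, 1 - ((mk$D - (mk$G + mk$HW) / 2) / pmax(1e-9, (mk$HW - mk$G) / 2))^2)),
    sqrt(pmax(0, 1 - (mk$D / pmax(1e-9, mk$HW))^2)))
  mu <- matrix(0, H, W)
  mu[mk$central] <- base * (0.55 + 0.65 * depth_central[mk$central])
  mu[mk$arms] <- base * 0.7
  # hotter spine band and periodic rib texture over trunk + pelvis rows
  rows <- seq_len(H)
  trunk_rows <- rows >= geom$shoulder_peak & rows <= geom$pelvis_end
  spine <- mk$central & matrix(trunk_rows, H, W) & mk$D <= 10 * geom$width_scale
  mu[spine] <- mu[spine] * 1.7
  rib_rows <- rows >= geom$shoulder_peak & rows <= geom$thorax_box["row1"]
  ribf <- 1 + 0.2 * sin(2 * pi * (rows - geom$shoulder_peak) / 14)
  ribs <- mk$central & matrix(rib_rows, H, W) & mk$D > 12 * geom$width_scale
  mu[ribs] <- mu[ribs] * matrix(ribf, H, W)[ribs]

  set.seed(params$noise_seed)
  dosage <- matrix(0L, H, W)
  nb <- sum(body)
  dosage[body] <- rpois(nb, mu[body])
  nout <- sum(!body)
  dosage[!body] <- as.integer(floor(runif(nout, 0, params$background_noise_max + 1)))

  # confounders: very hot, non-lesion uptake inside the body
  paint_disc <- function(dos, rr, cc, rad, value_mean) {
    grid <- expand.grid(row = (rr - rad):(rr + rad), col = (cc - rad):(cc + rad))
    keep <- (grid$row - rr)^2 + (grid$col - cc)^2 <= rad^2 &
      grid$row >= 1 & grid$row <= H & grid$col >= 1 & grid$col <= W
    idx <- cbind(grid$row[keep], grid$col[keep])
    idx <- idx[body[idx], , drop = FALSE]     # stay inside the body
    dos[idx] <- pmin(65535L, as.integer(value_mean + rpois(nrow(idx), 200)))
    dos
  }
  if (params$injection_point) {
    b <- phantom_bands(geom, H)
    rr <- as.integer(round((geom$trunk_start + geom$arm_end) / 2)) + sample(-20:20, 1L)
    side <- sample(c(-1, 1), 1L)
    off <- b$hw[rr] + geom$arm_gap + b$arm_w[rr] / 2
    dosage <- paint_disc(dosage, rr, as.integer(round(geom$centre + side * off)),
                         3L, sample(15000:30000, 1L))
  }
  if (params$bladder) {
    rr <- geom$pelvis_end - sample(10:20, 1L)
    dosage <- paint_disc(dosage, rr, geom$centre, 8L, sample(4000:8000, 1L))
  }

  # lesions: guaranteed at or above the hot-spot low bound
  lo <- params$hotspot_dosage_range[1]; hi <- params$hotspot_dosage_range[2]
  for (m in les$masks) {
    lesion_base <- if (hi > lo) sample(lo:hi, 1L) else lo
    vals <- lo + rpois(nrow(m), max(0L, lesion_base - lo))
    dosage[m] <- pmin(65535L, as.integer(vals))
  }

  storage.mode(dosage) <- "integer"
  label <- if (length(les$masks) > 0L) "metastasis" else "normal"
  truth <- structure(list(
    body_row_range = geom$body_row_range,
    thorax_box = geom$thorax_box,
    landmark_rows = c(head_peak = geom$head_peak,
                      elbow_peak = geom$elbow_peak,
                      shoulder_peak = geom$shoulder_peak,
                      leg_valley = geom$leg_valley),
    lesion_masks = les$masks,
    body_mask = body,
    label = label,
    subcategory = if (label == "normal") "none" else les$sub
  ), class = "phantom_truth")

  list(scan = body_scan(dosage, view = params$view), truth = truth)
}

#' Generate a cohort manifest of synthetic patients
#'
#' Emits a manifest with exactly `n_normal` normal and `n_metastasis`
#' metastasized scan records. Each simulated patient contributes an
#' anterior and a posterior view, except that with probability
#' `drop_rate` one of the two views is missing (emulating unsuccessfully
#' recorded examinations). Both views of a patient share anatomy (same
#' geometry seed) and label. Metastasis subcategories are allocated by
#' largest-remainder rounding of `subcategory_weights`, so the emitted
#' class mix matches the requested proportions up to rounding.
#'
#' @param n_normal,n_metastasis number of scan records per class.
#' @param subcategory_weights named or unnamed length-3 proportions for
#'   the `multiple`, `spinal` and `outside_spinal` subcategories (they
#'   are normalized to sum to 1). The default reproduces the class mix of
#'   a typical clinical bone-scan archive, where multi-focal disease
#'   dominates.
#' @param seed integer; drives view dropping, subcategory allocation and
#'   the per-scan seeds.
#' @param drop_rate probability that a patient is missing one view.
#' @param params_base a [phantom_params()] object used as a template for
#'   every scan (its view/seed/subcategory fields are overridden).
#' @return A data.frame manifest with columns `scan_id`, `patient_id`,
#'   `view`, `label`, `subcategory`, `rng_seed`, `noise_seed`. Use
#'   [cohort_scan()] to materialize a row.
#' @export
generate_cohort <- function(n_normal, n_metastasis,
                            subcategory_weights = c(multiple = 111, spinal = 14,
                                                    outside_spinal = 1),
                            seed = 1L,
                            drop_rate = 0.31,
                            params_base = phantom_params()) {
  n_normal <- as.integer(n_normal); n_metastasis <- as.integer(n_metastasis)
  if (n_normal < 0L || n_metastasis < 0L) {
    stop("generate_cohort: counts must be nonnegative", call. = FALSE)
  }
  empty <- data.frame(scan_id = character(), patient_id = character(),
                      view = character(), label = character(),
                      subcategory = character(), rng_seed = integer(),
                      noise_seed = integer(), stringsAsFactors = FALSE)
  if (n_normal + n_metastasis == 0L) return(empty)

  w <- subcategory_weights / sum(subcategory_weights)
  subs <- c("multiple", "spinal", "outside_spinal")
  # largest-remainder allocation of metastasis images to subcategories
  raw <- w * n_metastasis
  n_sub <- floor(raw)
  rem <- n_metastasis - sum(n_sub)
  if (rem > 0) {
    order_rem <- order(raw - n_sub, decreasing = TRUE)
    n_sub[order_rem[seq_len(rem)]] <- n_sub[order_rem[seq_len(rem)]] + 1
  }
  image_labels <- c(rep("normal", n_normal), rep.int(subs, n_sub))
  image_class <- c(rep("normal", n_normal), rep("metastasis", n_metastasis))

  set.seed(seed)
  rows <- list(); pid <- 0L
  i <- 1L
  while (i <= length(image_labels)) {
    pid <- pid + 1L
    remaining <- length(image_labels) - i + 1L
    two_views <- remaining >= 2L && image_class[i] == image_class[i + 1L] &&
      runif(1) >= drop_rate
    n_views <- if (two_views) 2L else 1L
    views <- if (n_views == 2L) c("anterior", "posterior") else
      sample(c("anterior", "posterior"), 1L)
    gseed <- sample.int(.Machine$integer.max - 4L, 1L)
    for (v in seq_len(n_views)) {
      sub <- image_labels[i]
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = sprintf("P%04d_%s", pid, substr(views[v], 1, 3)),
        patient_id = sprintf("P%04d", pid),
        view = views[v],
        label = if (sub == "normal") "normal" else "metastasis",
        subcategory = if (sub == "normal") "none" else sub,
        rng_seed = gseed,
        noise_seed = gseed + if (views[v] == "anterior") 1L else 2L,
        stringsAsFactors = FALSE
      )
      i <- i + 1L
    }
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "params_base") <- params_base
  manifest
}

#' Materialize one cohort manifest row as a scan
#'
#' @param manifest a manifest from [generate_cohort()].
#' @param i row index.
#' @param params_base template [phantom_params()]; defaults to the one
#'   recorded on the manifest.
#' @return As [generate_scan()]: `list(scan, truth)`.
#' @export
cohort_scan <- function(manifest, i, params_base = NULL) {
  if (is.null(params_base)) params_base <- attr(manifest, "params_base")
  if (is.null(params_base)) params_base <- phantom_params()
  row <- manifest[i, ]
  p <- params_base
  p$view <- row$view
  p$rng_seed <- row$rng_seed
  p$noise_seed <- row$noise_seed
  p$subcategory <- if (row$label == "normal") "none" else row$subcategory
  if (row$label == "normal") p$lesion_count_range <- c(0L, 0L)
  generate_scan(p)
}

#' Write a cohort to disk (DICOM + TIFF + JSON ground truth + CSV manifest)
#'
#' @param manifest a [generate_cohort()] manifest.
#' @param dir output directory (created if needed).
#' @param formats any of `"dcm"`, `"tiff"`.
#' @return The manifest with a `path` column, invisibly; also written as
#'   `manifest.csv`.
#' @export
write_cohort <- function(manifest, dir, formats = c("dcm", "tiff")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    g <- cohort_scan(manifest, i)
    stem <- file.path(dir, manifest$scan_id[i])
    if ("dcm" %in% formats) {
      write_scan_dcm(g$scan, paste0(stem, ".dcm"),
                     patient_id = manifest$patient_id[i])
      paths[i] <- paste0(stem, ".dcm")
    }
    if ("tiff" %in% formats) {
      write_scan_tiff(g$scan, paste0(stem, ".tif"))
      if (paths[i] == "") paths[i] <- paste0(stem, ".tif")
    }
    truth_json(g$truth, paste0(stem, ".json"))
  }
  manifest$path <- paths
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# JSON sidecar for ground truth (masks summarized as boxes; full masks are
# recomputable from the seeds in the manifest).
truth_json <- function(truth, path) {
  boxes <- lapply(truth$lesion_masks, function(m) {
    c(row0 = min(m[, "row"]), row1 = max(m[, "row"]),
      col0 = min(m[, "col"]), col1 = max(m[, "col"]),
      n_pixels = nrow(m))
  })
  jsonlite::write_json(list(
    body_row_range = unname(truth$body_row_range),
    thorax_box = as.list(truth$thorax_box),
    landmark_rows = as.list(truth$landmark_rows),
    lesion_boxes = boxes,
    label = truth$label,
    subcategory = truth$subcategory
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
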