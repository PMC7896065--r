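test_that("noise threshold equals the brute-force outside maximum", {
  expect_identical(noise_threshold(matrix(0L, 64, 32)), 0L)
  g <- default_phantom()
  outside <- !g$truth$body_mask
  oracle <- max(g$scan$dosage[outside])        # exhaustive scan of the mask
  expect_identical(noise_threshold(g$scan, outside_hint = outside), oracle)
  # the estimated outside region must agree on default phantoms
  expect_identical(noise_threshold(g$scan), oracle)
})

test_that("thresholding keeps every lesion pixel", {
  g <- default_phantom()
  thr <- noise_threshold(g$scan)
  clean <- strip_background(g$scan, thr + 1L)
  for (m in g$truth$lesion_masks) {
    expect_true(all(clean$dosage[m] > 0L))
  }
})

test_that("strip_background zeroes exactly the pixels below the threshold", {
  sc <- tiny_scan()
  expect_identical(strip_background(sc, 0L)$dosage, sc$dosage)  # identity
  expect_true(all(strip_background(sc, 1000L)$dosage == 0L))    # all below
  g <- default_phantom()
  thr <- 51L
  stripped <- strip_background(g$scan, thr)
  oracle_zeroed <- sum(g$scan$dosage < thr & g$scan$dosage > 0L)
  expect_identical(sum(stripped$dosage == 0L & g$scan$dosage > 0L),
                   oracle_zeroed + 0L)
  # idempotent
  expect_identical(strip_background(stripped, thr)$dosage, stripped$dosage)
})

test_that("body extent finds the first and last nonzero rows", {
  m <- matrix(0L, 1024, 256); m[100, 30] <- 900L
  expect_identical(unname(body_extent(m)), c(100L, 100L))
  m2 <- matrix(0L, 1024, 256); m2[5:900, 10] <- 700L
  expect_identical(unname(body_extent(m2)), c(5L, 900L))
  expect_error(body_extent(matrix(0L, 64, 32)), "empty body")
  g <- default_phantom()
  clean <- strip_background(g$scan, noise_threshold(g$scan) + 1L)
  ext <- body_extent(clean)
  expect_lte(abs(ext[1] - g$truth$body_row_range["top"]), 2L)
  expect_lte(abs(ext[2] - g$truth$body_row_range["bottom"]), 2L)
})

test_that("row profile counts nonzero pixels and flattens constant bodies", {
  m <- matrix(0L, 100, 50)
  m[10:90, 20:29] <- 500L                      # constant-width rectangle
  m[50, 30:34] <- 500L                         # one wider row
  pr <- row_profile(m, body_extent(m), smoothing_window = 5L)
  expect_identical(pr$counts[pr$rows == 20], 10)
  expect_identical(pr$counts[pr$rows == 50], 15)
  interior <- pr$rows > 20 & pr$rows < 45      # away from edges and the bump
  expect_true(all(abs(pr$d1[interior]) < 1e-9))
})

test_that("landmarks are the first three peaks and third valley", {
  # piecewise-linear profile with peaks planted at rows 40/180/260,
  # valleys at 110/220 and the third at 620, then a thigh bump at 700
  rows <- 1:800
  keys_r <- c(1, 40, 110, 180, 220, 260, 620, 700, 800)
  keys_v <- c(5, 60, 8, 150, 20, 140, 30, 95, 10)
  counts <- approx(keys_r, keys_v, xout = rows)$y
  profile <- structure(list(rows = rows, counts = counts,
                            fitted = counts,
                            d1 = c(0, diff(counts)), d2 = rep(0, 800),
                            smoothing_window = 1L),
                       class = "row_profile")
  lm <- landmark_rows(profile, peak_prominence_frac = 0.05)
  # brute-force extremum scan oracle on the constructed curve
  expect_identical(lm$head_peak, 40L)
  expect_identical(lm$elbow_peak, 180L)
  expect_identical(lm$shoulder_peak, 260L)
  expect_identical(lm$leg_valley, 620L)
})

test_that("a monotone profile raises a landmark error with partial results", {
  rows <- 1:200
  profile <- structure(list(rows = rows, counts = as.numeric(rows),
                            fitted = as.numeric(rows),
                            d1 = rep(1, 200), d2 = rep(0, 200),
                            smoothing_window = 1L),
                       class = "row_profile")
  err <- tryCatch(landmark_rows(profile), landmark_error = function(e) e)
  expect_s3_class(err, "landmark_error")
  expect_length(err$partial$peaks, 0L)
})

test_that("the 3:2 spine-to-pelvis split fixes the thorax bottom row", {
  g <- default_phantom()
  clean <- strip_background(g$scan, noise_threshold(g$scan) + 1L)
  pr <- row_profile(clean)
  lm <- landmark_rows(pr)
  lm$shoulder_peak <- 200L; lm$leg_valley <- 700L
  b <- thorax_bounds(lm, pr, clean)
  expect_identical(b$row0, 200L)
  expect_identical(b$row1, 500L)               # 200 + 3/5 * 500
  lm$leg_valley <- 200L
  expect_error(thorax_bounds(lm, pr, clean), "degenerate")
})

test_that("the crop is 256 x 256, conserves dosage and is deterministic", {
  g <- default_phantom()
  cp1 <- crop_pipeline(g$scan, crop_params(rng_seed = 7L))
  cp2 <- crop_pipeline(g$scan, crop_params(rng_seed = 7L))
  expect_identical(dim(cp1$thoracic$dosage), c(256L, 256L))
  expect_identical(cp1$thoracic$dosage, cp2$thoracic$dosage)
  expect_identical(cp1$sigma, cp2$sigma)
  expect_gt(cp1$sigma, 5); expect_lt(cp1$sigma, 15)
  # dosage conservation: sum inside the placed block equals the sum inside
  # the expanded source bounds
  eb <- cp1$thoracic$expanded_bounds
  clean <- strip_background(g$scan, cp1$thr_N + 1L)
  expect_identical(sum(as.double(cp1$thoracic$dosage)),
                   sum(as.double(clean$dosage[eb$row0:eb$row1, eb$col0:eb$col1])))
})

test_that("an oversized region is trimmed to the canvas with a warning", {
  m <- matrix(0L, 1024, 256)
  m[100:500, 20:240] <- 800L
  bounds <- structure(list(row0 = 100L, row1 = 450L, col0 = 20L, col1 = 240L),
                      class = "crop_bounds")
  expect_warning(out <- crop_thorax(m, bounds, sigma = 10), "trimming")
  expect_identical(dim(out$dosage), c(256L, 256L))
})

test_that("sigma outside (5, 15) is rejected", {
  bounds <- structure(list(row0 = 10L, row1 = 60L, col0 = 10L, col1 = 60L),
                      class = "crop_bounds")
  m <- matrix(1L, 128, 128)
  expect_error(crop_thorax(m, bounds, sigma = 5), "open interval")
  expect_error(crop_thorax(m, bounds, sigma = 16), "open interval")
  expect_error(crop_params(sigma = 20), "open interval")
})

test_that("the pipeline names the failing stage", {
  expect_error(crop_pipeline(matrix(0L, 1024, 256)), "stage2-extent")
})

test_that("thoracic crops contain the spinal and rib lesions", {
  for (s in c(31L, 32L, 33L)) {
    g <- generate_scan(phantom_params(rng_seed = s, subcategory = "multiple"))
    cp <- crop_pipeline(g$scan, crop_params(rng_seed = s))
    lesions <- do.call(rbind, g$truth$lesion_masks)
    inside <- spectmets:::map_to_crop(lesions, cp$thoracic)
    expect_gte(nrow(inside) / nrow(lesions), 0.9)
    # and the crop retains their dosage
    expect_gte(min(cp$thoracic$dosage[inside]), 3000L)
  }
})

test_that("anterior and posterior views crop to mirrored bounds", {
  a <- generate_scan(phantom_params(rng_seed = 13L, view = "anterior",
                                    lesion_count_range = c(0L, 0L)))
  p <- generate_scan(phantom_params(rng_seed = 13L, view = "posterior",
                                    lesion_count_range = c(0L, 0L)))
  ca <- crop_pipeline(a$scan, crop_params(rng_seed = 13L))
  cb <- crop_pipeline(p$scan, crop_params(rng_seed = 14L))
  two_sigma <- 2 * max(ca$sigma, cb$sigma)
  expect_lte(abs(ca$bounds$row0 - cb$bounds$row0), two_sigma)
  expect_lte(abs(ca$bounds$row1 - cb$bounds$row1), two_sigma)
  # columns mirror about the centre line
  expect_lte(abs(ca$bounds$col0 - (257 - cb$bounds$col1)), two_sigma)
  expect_lte(abs(ca$bounds$col1 - (257 - cb$bounds$col0)), two_sigma)
})
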