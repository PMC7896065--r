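#' Whole-body bone-scan image container
#'
#' A whole-body SPECT bone scan is a matrix of radiation-dosage counts
#' (16-bit unsigned integers), conventionally 256 pixels wide and 1024
#' high. The matrix is stored `[row, col]` with `nrow = height`,
#' `ncol = width`, 1-based, origin top-left.
#'
#' @param dosage integer matrix of nonnegative dosage counts.
#' @param view `"anterior"` or `"posterior"`.
#' @param patient_id opaque identifier string.
#' @param strict if `TRUE`, require the canonical 1024 x 256 dimensions.
#' @return An object of class `body_scan`.
#' @export
body_scan <- function(dosage, view = c("anterior", "posterior"),
                      patient_id = "", strict = FALSE) {
  view <- match.arg(view)
  if (!is.matrix(dosage)) stop("body_scan: dosage must be a matrix", call. = FALSE)
  storage.mode(dosage) <- "integer"
  if (anyNA(dosage) || min(dosage) < 0L || max(dosage) > 65535L) {
    stop("body_scan: dosage values must lie in [0, 65535]", call. = FALSE)
  }
  if (strict && !all(dim(dosage) == c(1024L, 256L))) {
    stop("body_scan: expected a 1024 x 256 (height x width) matrix, got ",
         nrow(dosage), " x ", ncol(dosage), call. = FALSE)
  }
  structure(list(dosage = dosage, view = view, patient_id = patient_id,
                 width = ncol(dosage), height = nrow(dosage)),
            class = "body_scan")
}

#' @export
print.body_scan <- function(x, ...) {
  cat(sprintf("<body_scan> %d x %d (h x w), view=%s, dosage range [%d, %d]\n",
              x$height, x$width, x$view, min(x$dosage), max(x$dosage)))
  invisible(x)
}

as_scan <- function(x) {
  if (inherits(x, "body_scan")) x else body_scan(x)
}

## ---------------------------------------------------------------------------
## Minimal single-frame DICOM (Explicit VR Little Endian)
##
## Bone-scan archives store each view as a single-frame 16-bit unsigned
## monochrome DICOM file. The writer emits the standard preamble, the group-2
## file meta header and a flat Explicit-VR-Little-Endian dataset; the reader
## parses exactly that profile and validates bit depth, frame count and
## sample representation, erroring with the violated expectation by name.
## ---------------------------------------------------------------------------

TRANSFER_SYNTAX_EVLE <- "1.2.840.10008.1.2.1"
SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.9.7435.1"

dcm_pad <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

dcm_element <- function(group, element, vr, value_raw) {
  tag <- writeBin(c(as.integer(group), as.integer(element)), raw(),
                  size = 2, endian = "little")
  if (vr %in% c("OB", "OW", "UN", "SQ", "UT")) {
    len <- writeBin(length(value_raw), raw(), size = 4, endian = "little")
    c(tag, charToRaw(vr), as.raw(c(0, 0)), len, value_raw)
  } else {
    len <- writeBin(length(value_raw), raw(), size = 2, endian = "little")
    c(tag, charToRaw(vr), len, value_raw)
  }
}

dcm_str <- function(group, element, vr, s) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  dcm_element(group, element, vr, dcm_pad(charToRaw(s), pad))
}

dcm_us <- function(group, element, v) {
  dcm_element(group, element, "US",
              writeBin(as.integer(v), raw(), size = 2, endian = "little"))
}

#' Write a scan as a single-frame 16-bit DICOM file
#'
#' Emits Explicit VR Little Endian with 16 bits allocated/stored, unsigned
#' pixel representation, MONOCHROME2 photometric interpretation and the
#' view recorded in Series Description.
#'
#' @param scan a [body_scan()] (or bare dosage matrix).
#' @param path output `.dcm` path.
#' @param patient_id overrides the scan's patient id when non-empty.
#' @return `path`, invisibly.
#' @export
write_scan_dcm <- function(scan, path, patient_id = "") {
  scan <- as_scan(scan)
  if (!nzchar(patient_id)) patient_id <- scan$patient_id
  if (!nzchar(patient_id)) patient_id <- "ANON"
  sop_uid <- paste0(IMPLEMENTATION_UID, ".",
                    sum(as.double(scan$dosage[seq_len(min(64, length(scan$dosage)))])) %% 1e6,
                    ".", scan$height, ".", scan$width)

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_str(0x0002, 0x0002, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EVLE),
    dcm_str(0x0002, 0x0012, "UI", IMPLEMENTATION_UID)
  )
  meta_len <- dcm_element(0x0002, 0x0000, "UL",
                          writeBin(length(meta), raw(), size = 4, endian = "little"))

  # PixelData is row-major (row by row); R matrices are column-major.
  px <- writeBin(as.integer(t(scan$dosage)), raw(), size = 2, endian = "little")
  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "NM"),
    dcm_str(0x0008, 0x103E, "LO", toupper(scan$view)),
    dcm_str(0x0010, 0x0020, "LO", patient_id),
    dcm_us(0x0028, 0x0002, 1L),                       # SamplesPerPixel
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_str(0x0028, 0x0008, "IS", "1"),               # NumberOfFrames
    dcm_us(0x0028, 0x0010, scan$height),              # Rows
    dcm_us(0x0028, 0x0011, scan$width),               # Columns
    dcm_us(0x0028, 0x0100, 16L),                      # BitsAllocated
    dcm_us(0x0028, 0x0101, 16L),                      # BitsStored
    dcm_us(0x0028, 0x0102, 15L),                      # HighBit
    dcm_us(0x0028, 0x0103, 0L),                       # PixelRepresentation
    dcm_element(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_len, meta, dataset), con)
  invisible(path)
}

dcm_format_error <- function(path, what) {
  stop(sprintf("read_scan: '%s' violates the expected format: %s",
               basename(path), what), call. = FALSE)
}

# Parse a flat Explicit-VR-Little-Endian byte stream into a tag list.
dcm_parse <- function(bytes, path) {
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  n <- length(bytes); pos <- 1L
  elems <- list()
  long_vrs <- c("OB", "OW", "UN", "SQ", "UT")
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      dcm_format_error(path, "not Explicit VR Little Endian (unreadable VR field)")
    }
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); val_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); val_at <- pos + 8L
    }
    if (val_at + len - 1L > n) dcm_format_error(path, "truncated element payload")
    value <- if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0)
    elems[[sprintf("%04X,%04X", group, element)]] <- list(vr = vr, value = value)
    pos <- val_at + len
  }
  elems
}

dcm_get_us <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NA_integer_)
  as.integer(e$value[1]) + 256L * as.integer(e$value[2])
}

dcm_get_str <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NA_character_)
  trimws(rawToChar(e$value[e$value != as.raw(0)]))
}

#' Read a whole-body bone scan
#'
#' Dispatches on extension: `.dcm` (single-frame 16-bit unsigned DICOM,
#' Explicit VR Little Endian) or `.tif`/`.tiff` (lossless 16-bit TIFF).
#' The returned matrix equals the stored pixel data exactly. Wrong bit
#' depth, signed pixels, multiple frames or out-of-bounds dimensions
#' raise a format error naming the violated expectation.
#'
#' @param path file path.
#' @param expect_dims optional `c(height, width)` to validate against.
#' @return A [body_scan()].
#' @export
read_scan <- function(path, expect_dims = NULL) {
  if (!file.exists(path)) {
    stop("read_scan: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  scan <- switch(ext,
    dcm = read_scan_dcm(path),
    tif = ,
    tiff = read_scan_tiff(path),
    stop("read_scan: unsupported extension '.", ext, "'", call. = FALSE)
  )
  if (!is.null(expect_dims) && !all(dim(scan$dosage) == expect_dims)) {
    dcm_format_error(path, sprintf("dimensions %d x %d, expected %d x %d",
                                   nrow(scan$dosage), ncol(scan$dosage),
                                   expect_dims[1], expect_dims[2]))
  }
  scan
}

read_scan_dcm <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 132L ||
      rawToChar(bytes[129:132]) != "DICM") {
    dcm_format_error(path, "missing DICM preamble")
  }
  elems <- dcm_parse(bytes[-(1:132)], path)
  ts <- dcm_get_str(elems, "0002,0010")
  if (!is.na(ts) && ts != TRANSFER_SYNTAX_EVLE) {
    dcm_format_error(path, paste0("unsupported transfer syntax ", ts))
  }
  bits <- dcm_get_us(elems, "0028,0100")
  if (is.na(bits) || bits != 16L) {
    dcm_format_error(path, sprintf("BitsAllocated = %s, expected 16", bits))
  }
  prep <- dcm_get_us(elems, "0028,0103")
  if (!is.na(prep) && prep != 0L) {
    dcm_format_error(path, "PixelRepresentation = 1 (signed), expected unsigned")
  }
  frames <- dcm_get_str(elems, "0028,0008")
  if (!is.na(frames) && as.integer(frames) != 1L) {
    dcm_format_error(path, paste0("NumberOfFrames = ", frames, ", expected 1"))
  }
  rows <- dcm_get_us(elems, "0028,0010")
  cols <- dcm_get_us(elems, "0028,0011")
  px <- elems[["7FE0,0010"]]
  if (is.null(px) || is.na(rows) || is.na(cols)) {
    dcm_format_error(path, "missing Rows/Columns/PixelData")
  }
  if (length(px$value) != 2L * rows * cols) {
    dcm_format_error(path, sprintf(
      "PixelData length %d does not match 16-bit %d x %d frame",
      length(px$value), rows, cols))
  }
  v <- readBin(px$value, "integer", n = rows * cols, size = 2,
               signed = FALSE, endian = "little")
  dosage <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  view <- tolower(dcm_get_str(elems, "0008,103E"))
  if (is.na(view) || !view %in% c("anterior", "posterior")) view <- "anterior"
  body_scan(dosage, view = view,
            patient_id = ifelse(is.na(dcm_get_str(elems, "0010,0020")), "",
                                dcm_get_str(elems, "0010,0020")))
}

#' Write / read a scan as lossless 16-bit TIFF
#'
#' @param scan a [body_scan()] or dosage matrix.
#' @param path file path.
#' @return `path` / a [body_scan()].
#' @export
write_scan_tiff <- function(scan, path) {
  scan <- as_scan(scan)
  tiff::writeTIFF(scan$dosage / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_scan_tiff
#' @export
read_scan_tiff <- function(path) {
  v <- tiff::readTIFF(path)
  body_scan(matrix(as.integer(round(v * 65535)), nrow(v), ncol(v)))
}

## ---------------------------------------------------------------------------
## LabelMe-style polygon annotations and the consensus rule
## ---------------------------------------------------------------------------

#' Read / write LabelMe-style annotation files
#'
#' One JSON file per image per doctor, holding a list of shapes, each with
#' a `label` string (a disease name or a body part) and `points`, a list
#' of `(row, col)` pixel vertices (1-based, origin top-left).
#'
#' @param path JSON file path.
#' @param shapes list of shapes; each `list(label =, points = matrix)` with
#'   a two-column `(row, col)` vertex matrix of at least 3 vertices.
#' @param image_dims optional `c(height, width)` bound check for vertices.
#' @return `read_annotation()` returns the shape list.
#' @export
read_annotation <- function(path, image_dims = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  shapes <- lapply(doc$shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) c(p[[1]], p[[2]])))
    colnames(pts) <- c("row", "col")
    list(label = s$label, points = pts)
  })
  validate_shapes(shapes, image_dims)
  shapes
}

#' @rdname read_annotation
#' @export
write_annotation <- function(shapes, path, image_dims = NULL) {
  validate_shapes(shapes, image_dims)
  doc <- list(shapes = lapply(shapes, function(s) {
    list(label = s$label,
         points = lapply(seq_len(nrow(s$points)),
                         function(i) as.list(unname(s$points[i, ]))))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_shapes <- function(shapes, image_dims = NULL) {
  for (s in shapes) {
    if (is.null(s$label) || !nzchar(s$label)) {
      stop("annotation: every shape needs a non-empty label", call. = FALSE)
    }
    if (!is.matrix(s$points) || nrow(s$points) < 3L) {
      stop("annotation: polygons need at least 3 vertices", call. = FALSE)
    }
    if (!is.null(image_dims)) {
      if (any(s$points[, 1] < 1) || any(s$points[, 1] > image_dims[1]) ||
          any(s$points[, 2] < 1) || any(s$points[, 2] > image_dims[2])) {
        stop("annotation: vertex coordinates outside image bounds", call. = FALSE)
      }
    }
  }
  invisible(shapes)
}

#' Labels that count as hot-spot (disease) annotations
#'
#' Shape labels are free text; a shape marks a hot spot when its label,
#' case-insensitively, matches one of these disease terms. Everything else
#' (body parts, fiducials) is ignored by the consensus rule.
#' @export
HOTSPOT_LABELS <- c("metastasis", "bone metastasis", "hotspot", "hot spot",
                    "hot_spot", "lesion", "tumor", "tumour")

#' Consensus image label from per-doctor annotations
#'
#' An image is labelled abnormal when at least two doctors each marked at
#' least one hot-spot area on it, and normal otherwise. Adding an
#' abnormal vote can never flip an abnormal call back to normal
#' (monotonicity).
#'
#' @param annotations list with one entry per doctor; each entry a list of
#'   shapes as returned by [read_annotation()] (possibly empty).
#' @param n_doctors number of annotating doctors; defaults to
#'   `length(annotations)`.
#' @param hotspot_labels character vector of labels that count as disease
#'   marks.
#' @param subcategory optional subcategory to attach to an abnormal call.
#' @return `list(label = "normal"|"abnormal", subcategory =, votes =)`.
#' @export
consensus_label <- function(annotations, n_doctors = length(annotations),
                            hotspot_labels = HOTSPOT_LABELS,
                            subcategory = NULL) {
  if (length(annotations) == 0L || n_doctors < 1L) {
    stop("consensus_label: empty annotation set", call. = FALSE)
  }
  votes <- vapply(annotations, function(doc) {
    any(vapply(doc, function(s) tolower(s$label) %in% tolower(hotspot_labels),
               logical(1)))
  }, logical(1))
  abnormal <- sum(votes) >= 2L
  list(
    label = if (abnormal) "abnormal" else "normal",
    subcategory = if (abnormal && !is.null(subcategory)) subcategory
                  else "none",
    votes = sum(votes)
  )
}
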