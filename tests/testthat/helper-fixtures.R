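# Shared fixtures, built in code.

# A tiny scan: mostly zeros with a rectangular "body" block.
tiny_scan <- function(h = 64L, w = 32L, body_rows = 20:50, body_cols = 10:24,
                      value = 500L) {
  m <- matrix(0L, h, w)
  m[body_rows, body_cols] <- value
  body_scan(m)
}

# One default phantom with lesions, cached per session (generation is not
# free and several tests only need *a* phantom).
default_phantom <- local({
  cache <- NULL
  function(seed = 11L) {
    if (is.null(cache)) {
      cache <<- generate_scan(phantom_params(rng_seed = seed,
                                             subcategory = "multiple"))
    }
    cache
  }
})

# Write a structurally valid DICOM, then rewrite its BitsAllocated element
# to the given value (byte-level surgery keeps everything else intact).
write_dcm_with_bits <- function(scan, path, bits) {
  write_scan_dcm(scan, path)
  bytes <- readBin(path, raw(), n = file.size(path))
  # (0028,0100) US, little endian: 28 00 00 01 'U' 'S' 02 00 <value>
  pat <- as.raw(c(0x28, 0x00, 0x00, 0x01, 0x55, 0x53, 0x02, 0x00))
  hit <- NA
  for (i in seq_len(length(bytes) - length(pat) - 1L)) {
    if (all(bytes[i:(i + 7L)] == pat)) { hit <- i; break }
  }
  stopifnot(!is.na(hit))
  bytes[hit + 8L] <- as.raw(bits %% 256L)
  bytes[hit + 9L] <- as.raw(bits %/% 256L)
  writeBin(bytes, path)
  path
}

# Simple polygon triangle shape for annotation tests.
tri_shape <- function(label, r = 10, c = 10) {
  list(label = label,
       points = rbind(c(r, c), c(r + 5, c), c(r, c + 5)))
}
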