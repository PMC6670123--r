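# shared fixtures and small-format writers, built in code at test time

# pipeline configuration used in tests: phantoms are generated directly at
# a 512-px / 3-mm working grid (the smallest grid the FAZ detector
# accepts), so upsampling is the identity and simulation studies stay fast
test_config <- function(...) rcd_config(target_px = 512L, ...)

# phantoms and their quantifications are cached per seed across tests
.fixtures <- new.env(parent = emptyenv())

default_phantom <- function(seed) {
  key <- paste0("ph", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_phantom(phantom_spec(seed = seed))
  .fixtures[[key]]
}

default_quant <- function(seed, layer = "SRCL") {
  key <- paste0("q", seed, layer)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- suppressWarnings(
      quantify_image(default_phantom(seed)$image, layer = layer,
                     config = test_config()))
  .fixtures[[key]]
}

# write an 8-bit grayscale PNG from a 0..255 matrix
write_png8 <- function(m, path = tempfile(fileext = ".png")) {
  png::writePNG(m / 255, path)
  path
}

# ---- minimal 16-bit grayscale PNG writer ----------------------------------
# png::writePNG emits 8-bit files only; the 16-bit input contract needs a
# real 16-bit fixture, built here from raw chunks (stored-deflate zlib).
.crc_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(-306674912L, bitwShiftR(c, 1)) else bitwShiftR(c, 1)
    tab[n + 1] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes))
    c <- bitwXor(bitwShiftR(c, 8), .crc_table[bitwAnd(bitwXor(c, b), 255L) + 1])
  bitwXor(c, -1L)
}

.u32be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

.png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(.u32be(length(data)), td, .u32be(.crc32(td)))
}

.zlib_stored <- function(data) {
  a <- 1; b <- 0
  for (x in as.integer(data)) { a <- (a + x) %% 65521; b <- (b + a) %% 65521 }
  n <- length(data)
  out <- as.raw(c(0x78, 0x01))
  i <- 1
  while (i <= n) {
    len <- min(65535, n - i + 1)
    final <- if (i + len > n) as.raw(1) else as.raw(0)
    out <- c(out, final, as.raw(len %% 256), as.raw(len %/% 256),
             as.raw(255 - len %% 256), as.raw(255 - len %/% 256),
             data[i:(i + len - 1)])
    i <- i + len
  }
  c(out, .u32be(b * 65536 + a))
}

# m: integer matrix of 16-bit samples in [0, 65535]
write_png16 <- function(m, path = tempfile(fileext = ".png")) {
  h <- nrow(m); w <- ncol(m)
  ihdr <- c(.u32be(w), .u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  vals <- as.integer(t(m))                       # row-major sample order
  dat <- rbind(vals %/% 256L, vals %% 256L)      # big-endian bytes
  rows <- matrix(as.integer(dat), nrow = 2 * w)  # one column per scanline
  scan <- as.raw(rbind(matrix(0L, 1, h), rows))  # filter byte 0 per row
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
             .png_chunk("IHDR", ihdr),
             .png_chunk("IDAT", .zlib_stored(scan)),
             .png_chunk("IEND", raw(0))), con)
  path
}
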