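# QR-style 2-D matrix barcode used to label plates.
#
# This is a self-contained symbology (not ISO/IEC 18004): square module grid
# with three QR-like 7x7 finder patterns in the top-left, top-right and
# bottom-left corners (each padded to an 8x8 reserved zone by a white
# separator), a quiet zone of 4 modules, and a payload stream of
# [length byte | payload bytes | CRC-32], bits MSB-first, laid row-major over
# the non-reserved modules.  Unused data modules carry a checkerboard fill so
# the symbol stays locally heterogeneous for the variance-filter locator.

CODE_SIZES <- seq(21L, 57L, by = 4L)

# bitwise xor on non-negative doubles < 2^32 (avoids 32-bit signed-int traps)
dxor32 <- function(a, b) {
  r <- 0; p <- 1
  for (i in 1:32) {
    ab <- a %% 2; bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2; b <- (b - bb) / 2
    p <- p * 2
  }
  r
}

crc32_bytes <- function(bytes) {
  crc <- 4294967295
  for (b in bytes) {
    crc <- dxor32(crc, b)
    for (k in 1:8) {
      lsb <- crc %% 2
      crc <- (crc - lsb) / 2
      if (lsb == 1) crc <- dxor32(crc, 3988292384) # 0xEDB88320
    }
  }
  crc <- 4294967295 - crc
  b3 <- crc %% 256; crc <- (crc - b3) / 256
  b2 <- crc %% 256; crc <- (crc - b2) / 256
  b1 <- crc %% 256; crc <- (crc - b1) / 256
  c(crc, b1, b2, b3) # big-endian
}

bytes_to_bits <- function(bytes) {
  as.vector(vapply(as.integer(bytes), function(b) {
    bits <- integer(8)
    for (i in 8:1) { bits[i] <- b %% 2L; b <- b %/% 2L }
    bits
  }, integer(8)))
}

bits_to_bytes <- function(bits) {
  n <- length(bits) %/% 8
  vapply(seq_len(n), function(i) {
    sum(bits[(8 * (i - 1) + 1):(8 * i)] * 2^(7:0))
  }, numeric(1))
}

# 8x8 reserved corner zones (finder + separator), TRUE where reserved
code_reserved_mask <- function(n) {
  res <- matrix(FALSE, n, n)
  res[1:8, 1:8] <- TRUE
  res[1:8, (n - 7):n] <- TRUE
  res[(n - 7):n, 1:8] <- TRUE
  res
}

# 7x7 finder: black ring, white ring, black 3x3 core
finder_pattern <- function() {
  f <- matrix(TRUE, 7, 7)
  f[2:6, 2:6] <- FALSE
  f[3:5, 3:5] <- TRUE
  f
}

# row-major linear indices of data modules
code_data_cells <- function(n) {
  res <- code_reserved_mask(n)
  idx <- which(!res, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

code_size_for <- function(nbits) {
  for (n in CODE_SIZES) if (n^2 - 3 * 64 >= nbits) return(n)
  rr_abort("rr_label_too_long", "payload too long for the largest symbol size")
}

# payload string -> logical module matrix (TRUE = black)
encode_matrix_code <- function(payload) {
  bytes <- as.integer(charToRaw(payload))
  if (length(bytes) > 255L)
    rr_abort("rr_label_too_long", "payload exceeds 255 bytes")
  stream <- c(length(bytes), bytes, crc32_bytes(c(length(bytes), bytes)))
  bits <- bytes_to_bits(stream)
  n <- code_size_for(length(bits))
  mod <- matrix(FALSE, n, n)
  f <- finder_pattern()
  mod[1:7, 1:7] <- f
  mod[1:7, (n - 6):n] <- f
  mod[(n - 6):n, 1:7] <- f
  cells <- code_data_cells(n)
  fill <- (cells[, 1] + cells[, 2]) %% 2 == 0 # checkerboard padding
  vals <- fill
  vals[seq_along(bits)] <- bits == 1
  mod[cells] <- vals
  mod
}

# Render the symbol as a white label filling `rect`, modules black.
# Modifies and returns the RGB array (0..255); also returns the symbol bbox.
render_code_into <- function(rgb, rect, payload) {
  mod <- encode_matrix_code(payload)
  n <- nrow(mod)
  m <- min(rect_height(rect), rect_width(rect)) %/% (n + 8L)
  if (m < 2L)
    rr_abort("rr_qr_rect_too_small",
             sprintf("barcode rect too small: needs >= %d px per side", 2L * (n + 8L)))
  rgb[rect$r0:rect$r1, rect$c0:rect$c1, ] <- 255
  side <- n * m
  r0 <- rect$r0 + (rect_height(rect) - side) %/% 2L
  c0 <- rect$c0 + (rect_width(rect) - side) %/% 2L
  big <- mod[rep(seq_len(n), each = m), rep(seq_len(n), each = m)]
  block <- rgb[r0:(r0 + side - 1L), c0:(c0 + side - 1L), ]
  for (ch in 1:3) {
    plane <- block[, , ch]
    plane[big] <- 0
    block[, , ch] <- plane
  }
  rgb[r0:(r0 + side - 1L), c0:(c0 + side - 1L), ] <- block
  list(rgb = rgb, symbol_rect = px_rect(r0, r0 + side - 1L, c0, c0 + side - 1L))
}

# grayscale crop (0..255 matrix, label plus some margin) -> payload string
decode_matrix_code <- function(gray) {
  fail <- function(msg) rr_abort("rr_qr_unreadable", msg)
  rng <- range(gray)
  if (diff(rng) < 50) fail("no symbol contrast")
  mid <- mean(rng)
  lc <- largest_component(gray > mid)
  if (is.null(lc)) fail("no bright label region")
  bb <- lc$bbox
  if (rect_height(bb) < 12 || rect_width(bb) < 12) fail("label region too small")
  inset <- px_rect(bb$r0 + 2L, bb$r1 - 2L, bb$c0 + 2L, bb$c1 - 2L)
  sub <- gray[inset$r0:inset$r1, inset$c0:inset$c1]
  dark <- sub < mid
  if (!any(dark)) fail("no modules found")
  w <- which(dark, arr.ind = TRUE)
  sym <- dark[min(w[, 1]):max(w[, 1]), min(w[, 2]):max(w[, 2]), drop = FALSE]
  srow0 <- inset$r0 + min(w[, 1]) - 1L
  scol0 <- inset$c0 + min(w[, 2]) - 1L
  # module pitch from the 7-module top edge of the top-left finder
  run <- which(!sym[1, ])[1]
  if (is.na(run) || run < 3) fail("cannot estimate module pitch")
  pitch0 <- (run - 1) / 7
  n_est <- round(ncol(sym) / pitch0)
  n <- CODE_SIZES[which.min(abs(CODE_SIZES - n_est))]
  pr <- nrow(sym) / n
  pc <- ncol(sym) / n
  if (pr < 1.5 || pc < 1.5) fail("symbol too small to sample")
  nr <- nrow(gray); ncg <- ncol(gray)
  bit_at <- function(i, j) { # i, j 1-based module indices
    r <- srow0 + round((i - 0.5) * pr) - 1L
    c <- scol0 + round((j - 0.5) * pc) - 1L
    rs <- clamp((r - 1L):(r + 1L), 1L, nr)
    cs <- clamp((c - 1L):(c + 1L), 1L, ncg)
    median(gray[rs, cs]) < mid
  }
  mod <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) mod[i, j] <- bit_at(i, j)
  # sanity: finder cores must be black, separators white
  if (!all(mod[3:5, 3:5]) || any(mod[8, 1:8]) || any(mod[1:8, 8]))
    fail("finder pattern check failed")
  cells <- code_data_cells(n)
  bits <- as.integer(mod[cells])
  len <- bits_to_bytes(bits[1:8])
  need <- (1 + len + 4) * 8
  if (len < 1 || need > length(bits)) fail("bad payload length")
  bytes <- bits_to_bytes(bits[seq_len(need)])
  body <- bytes[seq_len(len + 1)]
  crc <- bytes[(len + 2):(len + 5)]
  if (!isTRUE(all.equal(crc32_bytes(body), crc))) fail("CRC mismatch")
  rawToChar(as.raw(body[-1]))
}
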