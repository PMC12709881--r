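# Minimal BMP codec for 8-bit CT slices. Scanner exports use uncompressed
# BITMAPINFOHEADER files (8-bit palette or 24-bit BGR); nothing in the R
# imaging stack reads BMP, so the two routines below implement exactly that
# subset: no compression, bottom-up or top-down rows, 4-byte row padding.

# Read a BMP file into a numeric matrix (rows = y, cols = x) on 0..255.
# Colour input is collapsed to Rec.601 luminance.
readBMP <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "BM"))
    stop(sprintf("not a BMP file: %s", path), call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")      # file size
  readBin(con, "integer", 2, size = 2, endian = "little")      # reserved
  offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdrSize <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdrSize < 40)
    stop(sprintf("unsupported BMP header (size %d) in %s", hdrSize, path),
         call. = FALSE)
  width <- readBin(con, "integer", 1, size = 4, endian = "little")
  height <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")      # planes
  bpp <- readBin(con, "integer", 1, size = 2, endian = "little")
  compression <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (compression != 0)
    stop(sprintf("compressed BMP not supported: %s", path), call. = FALSE)
  if (!bpp %in% c(8L, 24L))
    stop(sprintf("unsupported BMP bit depth %d in %s", bpp, path), call. = FALSE)
  readBin(con, "integer", 5, size = 4, endian = "little")      # rest of header
  topDown <- height < 0
  height <- abs(height)
  palette <- NULL
  if (bpp == 8L) {
    seek(con, 14 + hdrSize)
    nEntries <- (offset - 14 - hdrSize) %/% 4
    if (nEntries < 1) stop(sprintf("8-bit BMP without palette: %s", path),
                           call. = FALSE)
    pal <- matrix(as.integer(readBin(con, "raw", nEntries * 4)), nrow = 4)
    # entries are B, G, R, reserved
    palette <- 0.299 * pal[3, ] + 0.587 * pal[2, ] + 0.114 * pal[1, ]
  }
  seek(con, offset)
  bytesPerPx <- bpp %/% 8
  rowSize <- ((width * bytesPerPx + 3) %/% 4) * 4
  raw <- readBin(con, "raw", rowSize * height)
  if (length(raw) < rowSize * height)
    stop(sprintf("truncated BMP pixel data: %s", path), call. = FALSE)
  rows <- matrix(as.integer(raw), nrow = rowSize)[seq_len(width * bytesPerPx), ,
                                                  drop = FALSE]
  if (bpp == 8L) {
    img <- t(rows)                         # height x width of palette indices
    img <- matrix(palette[img + 1L], nrow = height)
  } else {
    b <- t(rows[seq(1, width * 3, 3), , drop = FALSE])
    g <- t(rows[seq(2, width * 3, 3), , drop = FALSE])
    r <- t(rows[seq(3, width * 3, 3), , drop = FALSE])
    img <- 0.299 * r + 0.587 * g + 0.114 * b
  }
  if (!topDown) img <- img[rev(seq_len(height)), , drop = FALSE]
  round(img)
}

# Write a numeric matrix (0..255, rows = y) as an 8-bit grayscale palette BMP.
writeBMP <- function(img, path) {
  img <- round(img)
  if (min(img) < 0 || max(img) > 255)
    stop("BMP pixel values must lie in [0, 255]", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  rowSize <- ((w + 3) %/% 4) * 4
  con <- file(path, "wb")
  on.exit(close(con))
  offset <- 14L + 40L + 256L * 4L
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(offset + rowSize * h), con, size = 4, endian = "little")
  writeBin(c(0L, 0L), con, size = 2, endian = "little")
  writeBin(offset, con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                 # BI_RGB
  writeBin(as.integer(rowSize * h), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L), con, size = 4, endian = "little")    # 72 dpi
  writeBin(c(256L, 256L), con, size = 4, endian = "little")
  gray <- as.integer(0:255)
  writeBin(as.raw(rbind(gray, gray, gray, 0L)), con)             # B G R 0
  pad <- rowSize - w
  body <- matrix(as.raw(0L), nrow = rowSize, ncol = h)
  body[seq_len(w), ] <- as.raw(t(img[rev(seq_len(h)), , drop = FALSE]))
  writeBin(as.vector(body), con)
  invisible(path)
}
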