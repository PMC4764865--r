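# Minimal 8-bit greyscale BMP codec.
#
# Uncompressed BI_RGB, BITMAPINFOHEADER, 256-entry greyscale palette.
# Rows are stored bottom-up (the BMP default) and padded to 4-byte
# boundaries; top-down files (negative height) are also read.

#' Read an 8-bit greyscale BMP image
#'
#' Supports uncompressed 8-bit palette BMP files whose palette is a
#' grey ramp (each entry R = G = B); this is the dialect produced by CT
#' slice export and by [writeBMP()]. Returns intensities, not palette
#' indices, although for a grey ramp the two coincide.
#'
#' @param path file path.
#' @return integer matrix \code{[y, x]} with values in \code{[0, 255]}.
#' @seealso [writeBMP()], [loadStack()]
#' @export
readBMP <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path, call. = FALSE)
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  s32 <- function(off) { v <- u32(off); if (v >= 2^31) v - 2^32 else v }
  dataOffset <- u32(10L)
  headerSize <- u32(14L)
  if (headerSize < 40L)
    stop("unsupported BMP header in ", path, call. = FALSE)
  width <- s32(18L)
  height <- s32(22L)
  bpp <- u16(28L)
  compression <- u32(30L)
  if (bpp != 8L)
    stop(sprintf("%s is %d-bit; only 8-bit greyscale BMP is supported",
                 path, bpp), call. = FALSE)
  if (compression != 0L)
    stop("compressed BMP is not supported: ", path, call. = FALSE)
  topDown <- height < 0L
  height <- abs(height)
  # palette sits between header end and pixel data; verify grey ramp
  palStart <- 14L + headerSize
  nPal <- (dataOffset - palStart) / 4L
  if (nPal >= 1L) {
    pal <- matrix(as.integer(raw[palStart + seq_len(nPal * 4L)]),
                  ncol = 4L, byrow = TRUE)  # B, G, R, reserved
    if (any(pal[, 1L] != pal[, 2L] | pal[, 2L] != pal[, 3L]))
      stop("BMP palette is not greyscale: ", path, call. = FALSE)
    lut <- pal[, 1L]
  } else lut <- 0:255
  rowBytes <- ((width + 3L) %/% 4L) * 4L
  need <- dataOffset + rowBytes * height
  if (length(raw) < need)
    stop("truncated BMP file: ", path, call. = FALSE)
  px <- matrix(as.integer(raw[dataOffset + seq_len(rowBytes * height)]),
               nrow = rowBytes)[seq_len(width), , drop = FALSE]
  # columns of px are file rows (bottom-up unless topDown)
  img <- t(px)                       # rows = file rows, cols = x
  if (!topDown) img <- img[rev(seq_len(height)), , drop = FALSE]
  matrix(lut[img + 1L], nrow = height)
}

#' Write an 8-bit greyscale BMP image
#'
#' @param img integer matrix \code{[y, x]} with values in \code{[0, 255]}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readBMP()], [saveStack()]
#' @export
writeBMP <- function(img, path) {
  img <- as.matrix(img)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("image values must lie in [0, 255]", call. = FALSE)
  height <- nrow(img); width <- ncol(img)
  rowBytes <- ((width + 3L) %/% 4L) * 4L
  dataOffset <- 14L + 40L + 256L * 4L
  fileSize <- dataOffset + rowBytes * height
  u32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  u16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("BM", con, eos = NULL)
  u32(fileSize); u16(0L); u16(0L); u32(dataOffset)
  u32(40L); u32(width); u32(height)             # bottom-up
  u16(1L); u16(8L); u32(0L)                     # planes, bpp, BI_RGB
  u32(rowBytes * height); u32(2835L); u32(2835L)  # 72 dpi
  u32(256L); u32(0L)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))  # B, G, R, reserved
  writeBin(pal, con)
  body <- matrix(0L, nrow = rowBytes, ncol = height)
  body[seq_len(width), ] <- t(img[rev(seq_len(height)), , drop = FALSE])
  writeBin(as.raw(body), con)
  invisible(path)
}
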