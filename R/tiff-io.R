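# Baseline TIFF reader/writer (8-bit gray and 24-bit RGB, uncompressed,
# single plane, chunky planar configuration). Implemented here because no
# TIFF-capable R package is available in the target environment.

rd_int <- function(raw, offset, size, endian) {
  # offset is 0-based
  b <- as.integer(raw[(offset + 1):(offset + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a baseline TIFF file
#'
#' Supports uncompressed 8-bit grayscale (photometric 0 or 1) and 24-bit RGB
#' images with chunky planar configuration, little- or big-endian, one or
#' more strips.
#'
#' @param path TIFF file path.
#' @return numeric matrix (gray) or h x w x 3 array (RGB) of values 0-255.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file (bad byte order mark): ", path)
  if (rd_int(raw, 2, 2, endian) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd <- rd_int(raw, 4, 4, endian)
  nent <- rd_int(raw, ifd, 2, endian)
  tags <- list()
  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  for (i in seq_len(nent)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- rd_int(raw, e, 2, endian)
    typ <- rd_int(raw, e + 2, 2, endian)
    cnt <- rd_int(raw, e + 4, 4, endian)
    sz <- type_size[typ] * cnt
    voff <- if (sz <= 4) e + 8 else rd_int(raw, e + 8, 4, endian)
    unit <- if (typ %in% c(3)) 2 else if (typ %in% c(4)) 4 else 1
    vals <- vapply(seq_len(cnt), function(k) rd_int(raw, voff + (k - 1) * unit, unit, endian), numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  w <- g(256); h <- g(257)
  if (is.null(w) || is.null(h)) stop("malformed TIFF (missing dimensions): ", path)
  bits <- g(258, 8); comp <- g(259, 1); photo <- g(262, 1)
  spp <- g(277, 1); rps <- g(278, h)
  offs <- g(273); cnts <- g(279)
  if (comp != 1) stop("unsupported TIFF compression (only uncompressed supported): ", path)
  if (any(bits != 8)) stop("unsupported TIFF bit depth (only 8-bit supported): ", path)
  if (!spp %in% c(1, 3)) stop("unsupported samples per pixel: ", spp)
  if (g(284, 1) != 1) stop("unsupported planar configuration")
  data <- integer(0)
  for (k in seq_along(offs)) {
    s <- offs[k]
    data <- c(data, as.integer(raw[(s + 1):(s + cnts[k])]))
  }
  if (length(data) < h * w * spp) stop("truncated TIFF pixel data: ", path)
  data <- as.numeric(data[seq_len(h * w * spp)])
  if (spp == 1) {
    px <- matrix(data, nrow = h, ncol = w, byrow = TRUE)
    if (photo == 0) px <- 255 - px   # WhiteIsZero
    px
  } else {
    a <- array(0, dim = c(h, w, 3))
    m <- matrix(data, ncol = 3, byrow = TRUE)  # interleaved rgb per pixel
    for (c in 1:3) a[, , c] <- matrix(m[, c], nrow = h, ncol = w, byrow = TRUE)
    a
  }
}

#' Write a baseline TIFF file
#'
#' Writes uncompressed little-endian TIFF: 8-bit grayscale for a matrix,
#' 24-bit interleaved RGB for an h x w x 3 array.
#'
#' @param pixels numeric matrix or h x w x 3 array with values 0-255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pixels, path) {
  nd <- length(dim(pixels))
  if (!nd %in% c(2, 3)) stop("pixels must be a matrix or h x w x 3 array")
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  spp <- if (nd == 2) 1L else 3L
  px <- round(pixels)
  px[px < 0] <- 0; px[px > 255] <- 255
  if (spp == 1) {
    data <- as.raw(t(px))
  } else {
    inter <- rbind(as.vector(t(px[, , 1])), as.vector(t(px[, , 2])), as.vector(t(px[, , 3])))
    data <- as.raw(as.vector(inter))
  }
  dlen <- length(data)
  if (dlen %% 2 == 1) { data <- c(data, as.raw(0)); pad <- 1L } else pad <- 0L
  ifd_off <- 8L + dlen + pad

  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, typ, cnt, val) { u16(tag); u16(typ); u32(cnt)
    if (typ == 3 && cnt == 1) { u16(val); u16(0) } else u32(val) }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); u16(42L); u32(ifd_off)
  writeBin(data, con)
  nent <- 9L
  u16(nent)
  bps_off <- ifd_off + 2L + nent * 12L + 4L
  entry(256, 4, 1, w)
  entry(257, 4, 1, h)
  if (spp == 1) entry(258, 3, 1, 8) else entry(258, 3, 3, bps_off)
  entry(259, 3, 1, 1)
  entry(262, 3, 1, if (spp == 1) 1 else 2)
  entry(273, 4, 1, 8)
  entry(277, 3, 1, spp)
  entry(278, 4, 1, h)
  entry(279, 4, 1, dlen)
  u32(0L)  # no next IFD
  if (spp == 3) { u16(8L); u16(8L); u16(8L) }
  invisible(path)
}
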