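# ImageJ ROI file codec (.roi records and RoiSet .zip archives), written
# byte-level against the ImageJ format: 64-byte big-endian header, integer
# bounding-box-relative coordinates, optional sub-pixel float coordinates
# (options bit 128), 64-byte header2 carrying the name offset/length, and
# UTF-16BE name characters. Polygon (0), freeline (4), polyline (5),
# freehand (7), traced (8) and composite (rect + shape array) records are
# supported; line/oval/point records are rejected. Zip archives are written
# store-only (no compression) with a local CRC32, and read with R's internal
# unzip.

u16be <- function(x) as.raw(c(x %/% 256 %% 256, x %% 256))
u32be <- function(x) as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256,
                              x %/% 256 %% 256, x %% 256))
f32be <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "big")

rbe <- function(raw, off, size) {   # big-endian unsigned int, 0-based offset
  b <- as.integer(raw[(off + 1):(off + size)])
  sum(b * 256^(rev(seq_len(size)) - 1))
}
rbe_s16 <- function(raw, off) {
  v <- rbe(raw, off, 2)
  if (v >= 32768) v - 65536 else v
}
rfloatbe <- function(raw, off, n) {
  readBin(raw[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4, endian = "big")
}

encode_roi <- function(roi) {
  stopifnot(inherits(roi, "roi_polygon"))
  n <- length(roi$x)
  type <- if (roi$closed) 0L else 5L       # polygon / polyline
  left <- floor(min(roi$x)); top <- floor(min(roi$y))
  right <- floor(max(roi$x)) + 1L; bottom <- floor(max(roi$y)) + 1L
  xi <- pmax(0L, as.integer(floor(roi$x)) - left)
  yi <- pmax(0L, as.integer(floor(roi$y)) - top)
  h2off <- 64L + 12L * n
  name_utf <- utf8ToInt(roi$name)
  hdr <- c(charToRaw("Iout"), u16be(228L),
           as.raw(c(type, 0L)),
           u16be(top), u16be(left), u16be(bottom), u16be(right),
           u16be(n),
           raw(16),                         # x1,y1,x2,y2 floats unused
           u16be(0L),                       # stroke width
           u32be(0L),                       # shape roi size
           u32be(0L), u32be(0L),            # stroke / fill color
           u16be(0L),                       # subtype
           u16be(128L),                     # options: SUB_PIXEL_RESOLUTION
           as.raw(c(0L, 0L)),               # arrow style / head
           u16be(0L),                       # rounded rect arc
           u32be(0L),                       # position
           u32be(h2off))
  coords <- c(unlist(lapply(xi, u16be)), unlist(lapply(yi, u16be)),
              f32be(roi$x), f32be(roi$y))
  if (n == 0) coords <- raw(0)
  h2 <- raw(64)
  nm_off <- if (length(name_utf)) h2off + 64L else 0L
  h2[17:20] <- u32be(nm_off)               # NAME_OFFSET at header2 + 16
  h2[21:24] <- u32be(length(name_utf))     # NAME_LENGTH at header2 + 20
  name_bytes <- if (length(name_utf)) unlist(lapply(name_utf, u16be)) else raw(0)
  c(hdr, coords, h2, name_bytes)
}

encode_composite_roi <- function(paths, name = "") {
  # composite (shape-array) record: outer + hole paths, even-odd semantics
  vals <- numeric(0)
  allx <- unlist(lapply(paths, `[[`, "x")); ally <- unlist(lapply(paths, `[[`, "y"))
  for (p in paths) {
    vals <- c(vals, 0, p$x[1], p$y[1])
    for (i in seq_along(p$x)[-1]) vals <- c(vals, 1, p$x[i], p$y[i])
    vals <- c(vals, 4)
  }
  n_float <- length(vals)
  h2off <- 64L + 4L * n_float
  name_utf <- utf8ToInt(name)
  hdr <- c(charToRaw("Iout"), u16be(228L),
           as.raw(c(1L, 0L)),                       # type rect + shape array
           u16be(max(0, floor(min(ally)))), u16be(max(0, floor(min(allx)))),
           u16be(floor(max(ally)) + 1L), u16be(floor(max(allx)) + 1L),
           u16be(0L), raw(16), u16be(0L),
           u32be(n_float),
           u32be(0L), u32be(0L), u16be(0L), u16be(0L),
           as.raw(c(0L, 0L)), u16be(0L), u32be(0L), u32be(h2off))
  h2 <- raw(64)
  nm_off <- if (length(name_utf)) h2off + 64L else 0L
  h2[17:20] <- u32be(nm_off)
  h2[21:24] <- u32be(length(name_utf))
  name_bytes <- if (length(name_utf)) unlist(lapply(name_utf, u16be)) else raw(0)
  c(hdr, f32be(vals), h2, name_bytes)
}

decode_shape_array <- function(vals) {
  # composite ROI: java.awt PathIterator dump; segments MOVETO(0, 2 floats),
  # LINETO(1, 2), QUAD(2, 4), CUBIC(3, 6), CLOSE(4, 0)
  paths <- list(); cx <- numeric(0); cy <- numeric(0)
  i <- 1
  while (i <= length(vals)) {
    seg <- vals[i]
    if (seg == 0) {
      if (length(cx) >= 3) paths[[length(paths) + 1]] <- list(x = cx, y = cy)
      cx <- vals[i + 1]; cy <- vals[i + 2]; i <- i + 3
    } else if (seg == 1) {
      cx <- c(cx, vals[i + 1]); cy <- c(cy, vals[i + 2]); i <- i + 3
    } else if (seg == 4) {
      if (length(cx) >= 3) paths[[length(paths) + 1]] <- list(x = cx, y = cy)
      cx <- numeric(0); cy <- numeric(0); i <- i + 1
    } else stop("composite ROI with curved segments is not supported")
  }
  if (length(cx) >= 3) paths[[length(paths) + 1]] <- list(x = cx, y = cy)
  if (!length(paths)) stop("composite ROI contains no closed path")
  areas <- vapply(paths, function(p) shoelace_area(p$x, p$y), numeric(1))
  paths[[which.max(areas)]]
}

decode_roi <- function(raw, label = "") {
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("malformed ROI record", if (nzchar(label)) paste0(" [", label, "]"))
  version <- rbe(raw, 4, 2)
  type <- as.integer(raw[7])
  top <- rbe_s16(raw, 8); left <- rbe_s16(raw, 10)
  n <- rbe(raw, 16, 2)
  shape_size <- rbe(raw, 36, 4)
  options <- rbe(raw, 50, 2)
  h2off <- rbe(raw, 60, 4)
  name <- ""
  if (h2off > 0 && h2off + 64 <= length(raw)) {
    nm_off <- rbe(raw, h2off + 16, 4)
    nm_len <- rbe(raw, h2off + 20, 4)
    if (nm_len > 0 && nm_off + 2 * nm_len <= length(raw)) {
      codes <- vapply(seq_len(nm_len), function(k) rbe(raw, nm_off + 2 * (k - 1), 2), numeric(1))
      name <- intToUtf8(codes)
    }
  }
  if (type == 1 && shape_size > 0) {
    vals <- rfloatbe(raw, 64, shape_size)
    p <- decode_shape_array(vals)
    return(roi_polygon(p$x, p$y, name = name, closed = TRUE))
  }
  if (!type %in% c(0, 4, 5, 7, 8))
    stop("unsupported ROI record type ", type,
         " (only polygon/freehand/traced/polyline/composite records are supported)",
         if (nzchar(label)) paste0(" [", label, "]"))
  closed <- type %in% c(0, 7, 8)
  if (n == 0) stop("ROI record has no coordinates", if (nzchar(label)) paste0(" [", label, "]"))
  subpixel <- bitwAnd(options, 128L) != 0 && version >= 222
  if (subpixel && 64 + 12 * n <= length(raw)) {
    x <- rfloatbe(raw, 64 + 4 * n, n)
    y <- rfloatbe(raw, 64 + 8 * n, n)
  } else {
    x <- vapply(seq_len(n), function(k) left + rbe_s16(raw, 64 + 2 * (k - 1)), numeric(1))
    y <- vapply(seq_len(n), function(k) top + rbe_s16(raw, 64 + 2 * n + 2 * (k - 1)), numeric(1))
  }
  roi_polygon(x, y, name = name, closed = closed)
}

# ---- store-only zip container -------------------------------------------

crc32_raw <- function(data) cpp_crc32(data)

zip_store <- function(entries, path) {
  # entries: named list of raw vectors
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) {
    writeBin(as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256,
                      x %/% 16777216 %% 256)), con)
  }
  offs <- integer(length(entries)); crcs <- numeric(length(entries))
  pos <- 0L
  nms <- names(entries)
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    nm <- charToRaw(nms[i])
    offs[i] <- pos
    crcs[i] <- crc32_raw(data)
    writeBin(charToRaw("PK"), con); u16(0x0403)
    u16(20); u16(0); u16(0); u16(0); u16(0x21)   # version, flags, method, time, date
    u32(crcs[i]); u32(length(data)); u32(length(data))
    u16(length(nm)); u16(0)
    writeBin(nm, con); if (length(data)) writeBin(data, con)
    pos <- pos + 30L + length(nm) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    nm <- charToRaw(nms[i])
    writeBin(charToRaw("PK"), con); u16(0x0201)
    u16(20); u16(20); u16(0); u16(0); u16(0); u16(0x21)
    u32(crcs[i]); u32(length(entries[[i]])); u32(length(entries[[i]]))
    u16(length(nm)); u16(0); u16(0); u16(0); u16(0)
    u32(0)                                        # external attributes
    u32(offs[i])
    writeBin(nm, con)
    pos <- pos + 46L + length(nm)
  }
  writeBin(charToRaw("PK"), con); u16(0x0605)
  u16(0); u16(0); u16(length(entries)); u16(length(entries))
  u32(pos - cd_start); u32(cd_start); u16(0)
  invisible(path)
}

# ---- public archive API --------------------------------------------------

#' Read an ImageJ ROI archive
#'
#' Reads a single `.roi` record or a RoiSet `.zip` archive and returns one
#' [roi_polygon()] per record, in archive order, with vertex coordinates and
#' names preserved.
#'
#' @param path path to a `.roi` file or `.zip` archive.
#' @return list of `roi_polygon`.
#' @export
read_roi_archive <- function(path) {
  if (!file.exists(path)) stop("cannot read ROI archive: no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) >= 4 && rawToChar(raw[1:4]) == "Iout")
    return(list(decode_roi(raw, basename(path))))
  if (length(raw) >= 4 && identical(as.integer(raw[1:4]), c(80L, 75L, 5L, 6L)))
    return(list())  # zero-entry archive: bare end-of-central-directory record
  listing <- tryCatch(utils::unzip(path, list = TRUE, unzip = "internal"),
                      error = function(e) stop("not a .roi record or zip archive: ", path))
  if (nrow(listing) == 0) return(list())
  exdir <- tempfile("roiset")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  utils::unzip(path, exdir = exdir, unzip = "internal")
  lapply(seq_len(nrow(listing)), function(i) {
    f <- file.path(exdir, listing$Name[i])
    decode_roi(readBin(f, "raw", n = file.info(f)$size),
               label = sprintf("record %d: %s", i, listing$Name[i]))
  })
}

#' Write an ImageJ ROI archive
#'
#' Writes a RoiSet `.zip` archive (or a single `.roi` record when `path` ends
#' in `.roi` and one polygon is given) readable by [read_roi_archive()] and by
#' the ImageJ ROI manager. Sub-pixel coordinates are stored, so half-integer
#' crack-boundary vertices round-trip exactly.
#'
#' @param rois list of [roi_polygon()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_archive <- function(rois, path) {
  if (inherits(rois, "roi_polygon")) rois <- list(rois)
  if (grepl("\\.roi$", path)) {
    if (length(rois) != 1) stop("a single .roi file holds exactly one record")
    writeBin(encode_roi(rois[[1]]), path)
    return(invisible(path))
  }
  entries <- list()
  seen <- character(0)
  for (i in seq_along(rois)) {
    nm <- rois[[i]]$name
    if (!nzchar(nm)) nm <- sprintf("%04d", i)
    fn <- nm
    k <- 1
    while (fn %in% seen) { fn <- sprintf("%s-%d", nm, k); k <- k + 1 }
    seen <- c(seen, fn)
    entries[[paste0(fn, ".roi")]] <- encode_roi(rois[[i]])
  }
  zip_store(entries, path)
  invisible(path)
}
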