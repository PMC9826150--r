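#' Binary mask
#'
#' A raster of foreground/background pixels sharing the shape and calibration
#' of its source image. Foreground is stored logically and renders as 255,
#' background as 0.
#'
#' @param pixels logical matrix, or numeric matrix of `{0, 255}`.
#' @param scale_um_per_px positive calibration.
#' @return a `binary_mask`.
#' @export
binary_mask <- function(pixels, scale_um_per_px) {
  if (is.numeric(pixels)) {
    if (!all(pixels %in% c(0, 255))) stop("numeric mask values must be 0 or 255")
    pixels <- pixels == 255
  }
  if (!is.logical(pixels) || !is.matrix(pixels)) stop("pixels must be a logical matrix")
  if (scale_um_per_px <= 0) stop("scale_um_per_px must be positive")
  structure(list(pixels = pixels, scale_um_per_px = scale_um_per_px),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground (%.5g um^2)\n",
              ncol(x$pixels), nrow(x$pixels), sum(x$pixels), mask_area_um2(x)))
  invisible(x)
}

#' Foreground area of a mask in square micrometres
#'
#' Foreground pixel count times the squared calibration.
#' @param mask a `binary_mask`.
#' @return area in um^2.
#' @export
mask_area_um2 <- function(mask) {
  sum(mask$pixels) * mask$scale_um_per_px^2
}

#' Polygonal region of interest
#'
#' An ordered list of (x, y) pixel coordinates (0-based pixel centers) with a
#' text label. Closed polygons require at least three vertices.
#'
#' @param x,y numeric vertex coordinates.
#' @param name text label.
#' @param closed whether the outline is closed.
#' @return a `roi_polygon`.
#' @export
roi_polygon <- function(x, y, name = "", closed = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("polygon coordinates must not contain NA/NaN")
  if (closed && length(x) < 3) stop("a closed polygon needs at least 3 vertices")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 name = as.character(name), closed = isTRUE(closed)),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> '%s', %d vertices, %s (area %.5g px^2)\n",
              x$name, length(x$x), if (x$closed) "closed" else "open",
              if (x$closed) shoelace_area(x$x, x$y) else NA_real_))
  invisible(x)
}

#' Shoelace (signed-magnitude) polygon area
#'
#' @param x,y polygon vertices.
#' @return enclosed area (absolute value of the signed area).
#' @export
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(x, y, closed = TRUE) {
  n <- length(x)
  if (n < 2) return(0)
  i <- if (closed) c(seq_len(n)[-1], 1L) else seq_len(n)[-1]
  j <- if (closed) seq_len(n) else seq_len(n - 1)
  sum(sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
}

#' Rasterize a closed polygon onto an image grid
#'
#' Foreground pixels are those whose centers fall inside the polygon under
#' the even-odd rule; centers lying exactly on the boundary are included
#' (deterministic, epsilon-free tie rule).
#'
#' @param roi a closed `roi_polygon`.
#' @param shape integer `c(height, width)` of the target grid.
#' @param scale_um_per_px calibration for the resulting mask.
#' @return a `binary_mask`.
#' @export
rasterize_roi <- function(roi, shape, scale_um_per_px = 1) {
  if (!inherits(roi, "roi_polygon")) stop("roi must be an roi_polygon")
  if (!roi$closed) stop("cannot rasterize an open polygon")
  m <- cpp_rasterize(roi$x, roi$y, as.integer(shape[1]), as.integer(shape[2]))
  binary_mask(m, scale_um_per_px)
}

#' Exact Euclidean distance map
#'
#' Distance of every pixel to the nearest foreground pixel of the mask, in
#' pixels (exact squared-distance transform, no chamfer approximation).
#'
#' @param mask a `binary_mask` or logical matrix with at least one
#'   foreground pixel.
#' @return numeric matrix of distances (0 on foreground pixels).
#' @export
distance_map <- function(mask) {
  px <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  if (!any(px)) stop("distance_map needs at least one foreground pixel")
  sqrt(cpp_edt_sq(px))
}

#' Trace the outer crack boundary of a connected component
#'
#' Returns the closed polygon along the outer pixel-edge contour of the
#' requested foreground component. For hole-free 4-connected components the
#' shoelace area of the traced polygon equals the pixel count.
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @param component_id component number in 8-connected labeling order
#'   (column-major discovery); default 1 for single-component masks.
#' @param connectivity 4 or 8, the labeling connectivity.
#' @return a closed `roi_polygon` in pixel coordinates.
#' @export
trace_boundary <- function(mask, component_id = 1L, connectivity = 8) {
  px <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  lab <- cpp_label(px, as.integer(connectivity))
  if (max(lab) < component_id) stop("component ", component_id, " not found")
  v <- cpp_trace_crack(lab, as.integer(component_id))
  roi_polygon(v[, 1], v[, 2], name = as.character(component_id), closed = TRUE)
}
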