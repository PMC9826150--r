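#' Calibrated raster image
#'
#' The unit of all pipeline input: a 2D raster of 8-bit brightness values
#' (one gray channel or three RGB channels) together with its spatial
#' calibration in micrometres per pixel. Pixel (x, y) uses 0-based
#' pixel-center coordinates with x rightward and y downward; polygons are
#' stored in pixel units and the calibration is applied only at measurement
#' time.
#'
#' @param pixels numeric matrix (gray) or h x w x 3 array (RGB) of values in
#'   `[0, 255]`.
#' @param scale_um_per_px positive spatial calibration (micrometres per pixel).
#' @param channel_tag one of `"RGB"`, `"RED"`, `"GREEN"`, `"BLUE"`, `"GRAY"`.
#' @return A `calibrated_image` object.
#' @export
calibrated_image <- function(pixels, scale_um_per_px,
                             channel_tag = if (length(dim(pixels)) == 3) "RGB" else "GRAY") {
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  nd <- length(dim(pixels))
  if (nd == 2) {
    if (channel_tag == "RGB") stop("a single-channel image cannot be tagged RGB")
  } else if (nd == 3) {
    if (dim(pixels)[3] != 3L) stop("multi-channel images must have 3 channels")
    if (channel_tag != "RGB") stop("3-channel images must be tagged RGB")
  } else stop("pixels must be a matrix or an h x w x 3 array")
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1 ||
      is.na(scale_um_per_px) || scale_um_per_px <= 0)
    stop("scale_um_per_px must be a single positive number")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("brightness values must lie in [0, 255]")
  channel_tag <- match.arg(channel_tag, c("RGB", "RED", "GREEN", "BLUE", "GRAY"))
  structure(list(pixels = pixels, scale_um_per_px = scale_um_per_px,
                 channel_tag = channel_tag),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- image_dim(x)
  cat(sprintf("<calibrated_image> %d x %d px (%s), %.4g um/px, %.4g x %.4g um\n",
              d[2], d[1], x$channel_tag, x$scale_um_per_px,
              physical_width_um(x), d[1] * x$scale_um_per_px))
  invisible(x)
}

#' Image dimensions (rows = height, cols = width)
#' @param image a `calibrated_image` or `binary_mask`.
#' @return integer `c(height, width)`.
#' @export
image_dim <- function(image) {
  d <- dim(image$pixels)
  c(d[1], d[2])
}

#' Physical width of an image in micrometres
#'
#' Pixel width times the calibration.
#' @inheritParams image_dim
#' @return width in micrometres.
#' @export
physical_width_um <- function(image) {
  image_dim(image)[2] * image$scale_um_per_px
}

#' Extract a channel from a calibrated image
#'
#' RGB-to-gray conversion is the unweighted channel mean `(r + g + b) / 3`,
#' rounded half-up, matching the reference platform's default 8-bit
#' conversion. Extracting `GRAY` from a gray image is the identity.
#'
#' @param image a `calibrated_image`.
#' @param channel `"GRAY"`, `"RED"`, `"GREEN"`, `"BLUE"` or `"RGB"`.
#' @return a `calibrated_image` with the requested channel.
#' @export
extract_channel <- function(image, channel = c("GRAY", "RED", "GREEN", "BLUE", "RGB")) {
  channel <- match.arg(channel)
  nd <- length(dim(image$pixels))
  if (nd == 2) {
    if (channel %in% c("GRAY", image$channel_tag)) return(image)
    if (channel == "RGB") stop("cannot reconstruct RGB from a single channel")
    stop("image holds channel ", image$channel_tag, ", not ", channel)
  }
  px <- image$pixels
  out <- switch(channel,
    RGB   = return(image),
    RED   = px[, , 1],
    GREEN = px[, , 2],
    BLUE  = px[, , 3],
    GRAY  = floor((px[, , 1] + px[, , 2] + px[, , 3]) / 3 + 0.5))
  calibrated_image(matrix(out, dim(px)[1], dim(px)[2]),
                   image$scale_um_per_px, channel)
}

#' Read a TIFF image with a known calibration
#'
#' Reads a single-plane, 8-bit grayscale or 24-bit RGB baseline TIFF and
#' attaches the supplied calibration. The requested channel is extracted on
#' load (see [extract_channel()]).
#'
#' @param path path to a TIFF file.
#' @param scale_um_per_px positive calibration in micrometres per pixel.
#' @param channel channel selector, default `"GRAY"`.
#' @return a `calibrated_image`.
#' @export
read_image <- function(path, scale_um_per_px,
                       channel = c("GRAY", "RED", "GREEN", "BLUE", "RGB")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  px <- read_tiff(path)
  img <- calibrated_image(px, scale_um_per_px)
  extract_channel(img, channel)
}

#' Write a calibrated image as a baseline TIFF
#'
#' @param image a `calibrated_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  write_tiff(image$pixels, path)
  invisible(path)
}

as_gray_matrix <- function(image) {
  if (inherits(image, "calibrated_image")) {
    if (length(dim(image$pixels)) == 3) image <- extract_channel(image, "GRAY")
    image$pixels
  } else if (is.matrix(image)) image
  else stop("expected a calibrated_image or matrix")
}
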