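# Pore segmentation: global lumen/border thresholds and the Phansalkar
# local threshold for low-contrast images, distance-map morphology, and
# size/circularity filtering into an initial pore set. All thresholds are
# restricted to the cortical mask: no candidate pixel outside the cortex.

#' Threshold specification
#'
#' @param mode one of `"lumens"`, `"borders"`, `"lumens_plus_borders"`,
#'   `"phansalkar"`, `"try_all_union"`.
#' @param lumen_threshold integer 0-255; lumen pixels are those strictly
#'   above it.
#' @param border_threshold integer 0-255; border pixels are those strictly
#'   below it (absolute-black background excluded).
#' @param phansalkar_radius_px local neighborhood radius (default 15 px).
#' @param phansalkar_k,phansalkar_r,phansalkar_p,phansalkar_q constants of
#'   the Phansalkar threshold on the `[0, 1]`-normalized image; defaults are
#'   the published algorithm's values (k 0.25, r 0.5, p 2, q 10).
#' @return a `threshold_spec`.
#' @export
threshold_spec <- function(mode = c("lumens_plus_borders", "lumens", "borders",
                                    "phansalkar", "try_all_union"),
                           lumen_threshold = 200L, border_threshold = 100L,
                           phansalkar_radius_px = 15L, phansalkar_k = 0.25,
                           phansalkar_r = 0.5, phansalkar_p = 2.0,
                           phansalkar_q = 10.0) {
  mode <- match.arg(mode)
  if (mode %in% c("lumens", "lumens_plus_borders", "try_all_union") &&
      (lumen_threshold < 0 || lumen_threshold > 255))
    stop("lumen_threshold must be in [0, 255]")
  if (mode %in% c("borders", "lumens_plus_borders", "try_all_union") &&
      (border_threshold < 0 || border_threshold > 255))
    stop("border_threshold must be in [0, 255]")
  if (phansalkar_radius_px < 1) stop("phansalkar_radius_px must be at least 1")
  structure(list(mode = mode, lumen_threshold = lumen_threshold,
                 border_threshold = border_threshold,
                 phansalkar_radius_px = as.integer(phansalkar_radius_px),
                 phansalkar_k = phansalkar_k, phansalkar_r = phansalkar_r,
                 phansalkar_p = phansalkar_p, phansalkar_q = phansalkar_q),
            class = "threshold_spec")
}

#' Morphological modification specification
#'
#' @param close_fill_cycles closing radius in pixels (dilation then erosion
#'   via the distance map, holes filled in between).
#' @param smooth_cycles opening radius in pixels (erosion then dilation).
#' @param min_size_um2 minimum pore area; survivors are strictly larger.
#' @param min_circularity minimum circularity in `[0, 1]`; survivors are
#'   strictly above it.
#' @return a `morph_spec`.
#' @export
morph_spec <- function(close_fill_cycles = 2L, smooth_cycles = 2L,
                       min_size_um2 = 2000, min_circularity = 0.300) {
  if (close_fill_cycles < 0 || smooth_cycles < 0 || min_size_um2 < 0)
    stop("morph_spec parameters must be non-negative")
  if (min_circularity < 0 || min_circularity > 1)
    stop("min_circularity must be in [0, 1]")
  structure(list(close_fill_cycles = as.integer(close_fill_cycles),
                 smooth_cycles = as.integer(smooth_cycles),
                 min_size_um2 = min_size_um2,
                 min_circularity = min_circularity),
            class = "morph_spec")
}

cortex_logical <- function(cortical_mask, g) {
  if (is.null(cortical_mask)) g > 0 else cortical_mask$pixels
}

#' Global lumen threshold
#'
#' Foreground where the gray value strictly exceeds `t` and the pixel lies
#' inside the cortical mask (near-white pore lumens).
#'
#' @param gray a cleared grayscale `calibrated_image`.
#' @param t threshold 0-255.
#' @param cortical_mask optional [binary_mask()]; defaults to all nonzero
#'   pixels of the cleared image.
#' @return a [binary_mask()].
#' @export
threshold_lumens <- function(gray, t, cortical_mask = NULL) {
  if (t < 0 || t > 255) stop("threshold must be in [0, 255]")
  g <- as_gray_matrix(gray)
  binary_mask((g > t) & cortex_logical(cortical_mask, g), gray$scale_um_per_px)
}

#' Global border threshold
#'
#' Foreground where `0 < value < t` inside the cortical mask (dark pore
#' borders; the absolute-black cleared background is excluded).
#'
#' @inheritParams threshold_lumens
#' @return a [binary_mask()].
#' @export
threshold_borders <- function(gray, t, cortical_mask = NULL) {
  if (t < 0 || t > 255) stop("threshold must be in [0, 255]")
  g <- as_gray_matrix(gray)
  binary_mask((g > 0) & (g < t) & cortex_logical(cortical_mask, g),
              gray$scale_um_per_px)
}

#' Phansalkar local threshold
#'
#' Per-pixel threshold `T = m * (1 + p * exp(-q * m) + k * ((s / r) - 1))`
#' with `m`, `s` the local mean and standard deviation of the
#' `[0, 1]`-normalized image in a disk of the given radius; a pixel is
#' foreground when its normalized value exceeds `T` (bright-object
#' convention). Designed for low-contrast images.
#'
#' @param gray a grayscale `calibrated_image`.
#' @param spec a [threshold_spec()] carrying the Phansalkar constants.
#' @param cortical_mask optional cortical restriction.
#' @return a [binary_mask()].
#' @export
threshold_phansalkar <- function(gray, spec = threshold_spec("phansalkar"),
                                 cortical_mask = NULL) {
  g <- as_gray_matrix(gray)
  gn <- g / 255
  st <- cpp_local_mean_sd(gn, spec$phansalkar_radius_px)
  Tm <- st$mean * (1 + spec$phansalkar_p * exp(-spec$phansalkar_q * st$mean) +
                     spec$phansalkar_k * ((st$sd / spec$phansalkar_r) - 1))
  fg <- gn > Tm
  if (!is.null(cortical_mask)) fg <- fg & cortical_mask$pixels
  binary_mask(fg, gray$scale_um_per_px)
}

#' Pixelwise union of binary masks
#'
#' @param masks list of [binary_mask()] of identical shape.
#' @return the union mask.
#' @export
combine_masks <- function(masks) {
  if (!length(masks)) stop("no masks to combine")
  d <- dim(masks[[1]]$pixels)
  out <- matrix(FALSE, d[1], d[2])
  for (m in masks) {
    if (!all(dim(m$pixels) == d)) stop("mask shapes differ")
    out <- out | m$pixels
  }
  binary_mask(out, masks[[1]]$scale_um_per_px)
}

binary_dilate <- function(px, n) {
  if (n <= 0) return(px)
  px | (cpp_edt_sq(px) <= n^2)
}

binary_erode <- function(px, n) {
  if (n <= 0) return(px)
  px & !(cpp_edt_sq(!px) <= n^2)
}

#' Single-pixel closing and hole filling
#'
#' One dilation then one erosion with a 3x3 structuring element, followed by
#' filling of all 4-connected background holes that do not touch the image
#' border.
#'
#' @param mask a [binary_mask()].
#' @return the closed, filled mask.
#' @export
close_and_fill <- function(mask) {
  px <- mask$pixels
  dil <- px
  for (dy in -1:1) for (dx in -1:1)
    dil <- dil | shift_mat(px, dy, dx, fill = FALSE)
  ero <- dil
  for (dy in -1:1) for (dx in -1:1)
    ero <- ero & shift_mat(dil, dy, dx, fill = TRUE)
  binary_mask(fill_holes(ero, connectivity = 4), mask$scale_um_per_px)
}

shift_mat <- function(m, dy, dx, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ydst <- max(1, 1 + dy):min(h, h + dy)
  xdst <- max(1, 1 + dx):min(w, w + dx)
  out[ydst, xdst] <- m[ydst - dy, xdst - dx]
  out
}

#' Distance-map morphological modification
#'
#' Closing (`close_fill_cycles` pixels) is a single Euclidean-distance-map
#' dilation by n followed by hole filling and an EDM erosion by n; smoothing
#' (`smooth_cycles`) is an EDM opening (erosion then dilation). A single EDM
#' pass per direction avoids the deformation artifacts of iterated 3x3
#' cycles. Zero cycles is the identity.
#'
#' @param mask a [binary_mask()].
#' @param spec a [morph_spec()].
#' @return the modified mask.
#' @export
morph_modify <- function(mask, spec = morph_spec()) {
  px <- mask$pixels
  n <- spec$close_fill_cycles
  if (n > 0) {
    px <- binary_dilate(px, n)
    px <- fill_holes(px, 4)
    px <- binary_erode(px, n)
  }
  m <- spec$smooth_cycles
  if (m > 0) {
    px <- binary_erode(px, m)
    px <- binary_dilate(px, m)
  }
  binary_mask(px, mask$scale_um_per_px)
}

#' Filter candidate components into an initial pore set
#'
#' Labels connected components (8-connected) and keeps those with area
#' strictly above `min_size_um2` and circularity strictly above
#' `min_circularity` (the same capped `4 * pi * A / P^2` used in
#' morphometry). Each survivor becomes one row of a pore table with its
#' traced crack-boundary polygon.
#'
#' @param mask a [binary_mask()].
#' @param spec a [morph_spec()].
#' @param perimeter_convention `"kulpa"` (corner-corrected chain, default)
#'   or `"crack"` (raw rectilinear).
#' @return a `pore_set` tibble (see [measure_components()]).
#' @export
filter_candidates <- function(mask, spec = morph_spec(),
                              perimeter_convention = c("kulpa", "crack")) {
  perimeter_convention <- match.arg(perimeter_convention)
  pores <- measure_components(mask, perimeter_convention = perimeter_convention)
  keep <- pores$area_um2 > spec$min_size_um2 &
    pores$circularity > spec$min_circularity
  out <- pores[keep, , drop = FALSE]
  out$id <- seq_len(nrow(out))
  out
}

#' Segment pores from a cleared image
#'
#' Full segmentation stage: threshold per the spec (with `try_all_union`
#' taking the union of every mechanism), single-pixel close-and-fill,
#' distance-map morphology, and the size/circularity filter.
#'
#' @param cleared a cleared grayscale `calibrated_image`.
#' @param borders a [border_set()] (restricts candidates to the cortex).
#' @param tspec a [threshold_spec()].
#' @param mspec a [morph_spec()].
#' @param perimeter_convention passed to [filter_candidates()].
#' @return a `pore_set` tibble.
#' @export
extract_pores <- function(cleared, borders, tspec = threshold_spec(),
                          mspec = morph_spec(),
                          perimeter_convention = c("kulpa", "crack")) {
  perimeter_convention <- match.arg(perimeter_convention)
  cm <- borders$cortical_mask
  gray <- extract_channel(cleared, "GRAY")
  masks <- switch(tspec$mode,
    lumens = list(threshold_lumens(gray, tspec$lumen_threshold, cm)),
    borders = list(threshold_borders(gray, tspec$border_threshold, cm)),
    lumens_plus_borders = list(threshold_lumens(gray, tspec$lumen_threshold, cm),
                               threshold_borders(gray, tspec$border_threshold, cm)),
    phansalkar = list(threshold_phansalkar(gray, tspec, cm)),
    try_all_union = list(threshold_lumens(gray, tspec$lumen_threshold, cm),
                         threshold_borders(gray, tspec$border_threshold, cm),
                         threshold_phansalkar(gray, tspec, cm)))
  m <- combine_masks(masks)
  m <- close_and_fill(m)
  m <- morph_modify(m, mspec)
  # re-clip to the cortex after morphology
  m <- binary_mask(m$pixels & cm$pixels, m$scale_um_per_px)
  filter_candidates(m, mspec, perimeter_convention)
}
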