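# Per-pore shape descriptors and whole-section cross-sectional geometry:
# area, perimeter (corner-corrected chain or raw crack convention),
# circularity, Feret calipers on the convex hull, moments-based ellipse fit,
# roundness, solidity, principal centroidal second moments of area and the
# polar section modulus.

KULPA_STRAIGHT <- 0.948
KULPA_DIAGONAL <- 1.340

convex_hull_xy <- function(x, y) {
  i <- grDevices::chull(x, y)
  list(x = x[i], y = y[i])
}

feret_diameters <- function(x, y) {
  h <- convex_hull_xy(x, y)
  n <- length(h$x)
  if (n == 1) return(c(max = 0, min = 0))
  if (n == 2) {
    d <- sqrt(diff(h$x)^2 + diff(h$y)^2)
    return(c(max = d, min = 0))
  }
  dmax <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- (h$x[i] - h$x[j])^2 + (h$y[i] - h$y[j])^2
    if (d > dmax) dmax <- d
  }
  # min caliper width: for each hull edge, the farthest vertex distance
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- h$x[j] - h$x[i]; ey <- h$y[j] - h$y[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    d <- abs((h$x - h$x[i]) * ey - (h$y - h$y[i]) * ex) / len
    wmin <- min(wmin, max(d))
  }
  c(max = sqrt(dmax), min = wmin)
}

ellipse_axes_px <- function(xs, ys) {
  # moments-based fit: orientation and axis ratio from central second
  # moments (pixel centers + 1/12 per-pixel correction), axes scaled so the
  # ellipse area equals the region area
  n <- length(xs)
  xc <- mean(xs); yc <- mean(ys)
  mxx <- sum((xs - xc)^2) / n + 1 / 12
  myy <- sum((ys - yc)^2) / n + 1 / 12
  mxy <- sum((xs - xc) * (ys - yc)) / n
  tr <- (mxx + myy) / 2
  det <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr + det; l2 <- max(tr - det, 1e-12)
  a0 <- 2 * sqrt(l1); b0 <- 2 * sqrt(l2)
  f <- sqrt(n / (pi * a0 * b0))
  c(major = 2 * a0 * f, minor = 2 * b0 * f,
    angle = atan2(2 * mxy, mxx - myy) / 2)
}

chain_perimeter_px <- function(lab, id) {
  ch <- cpp_moore_chain(lab, id)
  if (sum(ch) == 0) return(4)        # isolated pixel
  KULPA_STRAIGHT * ch[1] + KULPA_DIAGONAL * ch[2]
}

pore_metrics_row <- function(poly, xs, ys, scale, perim_px) {
  area_px <- length(xs)
  area <- area_px * scale^2
  perim <- perim_px * scale
  fer <- feret_diameters(poly$x, poly$y) * scale
  ell <- ellipse_axes_px(xs, ys)
  hull <- convex_hull_xy(poly$x, poly$y)
  hull_area <- shoelace_area(hull$x, hull$y) * scale^2
  major <- ell["major"] * scale; minor <- ell["minor"] * scale
  tibble::tibble(
    area_um2 = area,
    perimeter_um = perim,
    circularity = min(1, 4 * pi * area / perim^2),
    feret_max_um = unname(fer["max"]),
    feret_min_um = unname(fer["min"]),
    ellipse_major_um = unname(major),
    ellipse_minor_um = unname(minor),
    aspect_ratio = unname(major / minor),
    roundness = min(1, unname(4 * area / (pi * major^2))),
    solidity = min(1, area / hull_area))
}

#' Measure every connected component of a mask
#'
#' Labels the mask (8-connected) and measures each component: area,
#' perimeter, circularity, Feret diameters (rotating calipers on the convex
#' hull of the crack polygon), moments-fit ellipse axes, aspect ratio,
#' roundness and solidity. Returns one row per component with the boundary
#' polygon and pixel list carried as list-columns.
#'
#' @param mask a [binary_mask()].
#' @param perimeter_convention `"kulpa"` (default): corner-corrected
#'   8-connected chain (0.948/straight, 1.340/diagonal step);
#'   `"crack"`: raw rectilinear crack-polygon length.
#' @param connectivity labeling connectivity (default 8).
#' @return a `pore_set` tibble with columns `id`, `name`, the metric columns
#'   of the morphometric report, `centroid_x/y`, and list-columns `polygon`
#'   and `pixels` (1-based matrix indices).
#' @export
measure_components <- function(mask, perimeter_convention = c("kulpa", "crack"),
                               connectivity = 8) {
  perimeter_convention <- match.arg(perimeter_convention)
  scale <- mask$scale_um_per_px
  lab <- cpp_label(mask$pixels, as.integer(connectivity))
  k <- max(lab)
  rows <- vector("list", k)
  h <- nrow(lab)
  for (id in seq_len(k)) {
    idx <- which(lab == id)
    ys <- (idx - 1) %% h          # 0-based pixel y
    xs <- (idx - 1) %/% h         # 0-based pixel x
    poly <- cpp_trace_crack(lab, id)
    poly <- roi_polygon(poly[, 1], poly[, 2], name = sprintf("%04d", id), closed = TRUE)
    perim_px <- if (perimeter_convention == "kulpa") chain_perimeter_px(lab, id)
                else polygon_perimeter(poly$x, poly$y)
    m <- pore_metrics_row(poly, xs, ys, scale, perim_px)
    m$id <- id
    m$name <- poly$name
    m$centroid_x <- mean(xs)
    m$centroid_y <- mean(ys)
    m$polygon <- list(poly)
    m$pixels <- list(idx)
    rows[[id]] <- m
  }
  out <- if (k == 0) empty_pore_set() else do.call(rbind, rows)
  out <- out[, pore_set_columns()]
  attr(out, "scale_um_per_px") <- scale
  attr(out, "image_dim") <- dim(mask$pixels)
  class(out) <- c("pore_set", class(out))
  out
}

pore_set_columns <- function() {
  c("id", "name", "area_um2", "perimeter_um", "circularity", "feret_max_um",
    "feret_min_um", "ellipse_major_um", "ellipse_minor_um", "aspect_ratio",
    "roundness", "solidity", "centroid_x", "centroid_y", "polygon", "pixels")
}

empty_pore_set <- function() {
  tibble::tibble(id = integer(0), name = character(0), area_um2 = numeric(0),
                 perimeter_um = numeric(0), circularity = numeric(0),
                 feret_max_um = numeric(0), feret_min_um = numeric(0),
                 ellipse_major_um = numeric(0), ellipse_minor_um = numeric(0),
                 aspect_ratio = numeric(0), roundness = numeric(0),
                 solidity = numeric(0), centroid_x = numeric(0),
                 centroid_y = numeric(0), polygon = list(), pixels = list())
}

#' Measure a single pore
#'
#' Measures a pore given its boundary polygon (and optionally its raster
#' mask; rasterized from the polygon when absent).
#'
#' @param polygon closed [roi_polygon()] in pixel coordinates.
#' @param scale_um_per_px calibration.
#' @param shape image shape `c(height, width)`; default tight bounding box.
#' @param perimeter_convention see [measure_components()].
#' @return a one-row metrics tibble.
#' @export
measure_pore <- function(polygon, scale_um_per_px, shape = NULL,
                         perimeter_convention = c("kulpa", "crack")) {
  perimeter_convention <- match.arg(perimeter_convention)
  if (is.null(shape)) shape <- c(ceiling(max(polygon$y)) + 2, ceiling(max(polygon$x)) + 2)
  mask <- rasterize_roi(polygon, shape, scale_um_per_px)
  if (sum(mask$pixels) < 1) stop("degenerate pore: no pixels under the polygon")
  lab <- cpp_label(mask$pixels, 8L)
  idx <- which(mask$pixels)
  h <- nrow(mask$pixels)
  perim_px <- if (perimeter_convention == "kulpa") chain_perimeter_px(lab, 1L)
              else polygon_perimeter(polygon$x, polygon$y)
  pore_metrics_row(polygon, (idx - 1) %/% h, (idx - 1) %% h,
                   scale_um_per_px, perim_px)
}

second_moments_mm4 <- function(mask) {
  scale <- mask$scale_um_per_px
  idx <- which(mask$pixels)
  h <- nrow(mask$pixels)
  ys <- (idx - 1) %% h; xs <- (idx - 1) %/% h
  n <- length(idx)
  xc <- mean(xs); yc <- mean(ys)
  ixx <- sum((ys - yc)^2) + n / 12        # about the horizontal axis
  iyy <- sum((xs - xc)^2) + n / 12
  ixy <- sum((xs - xc) * (ys - yc))
  tr <- (ixx + iyy) / 2
  det <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  um4_to_mm4 <- 1e-12
  list(imin = (tr - det) * scale^4 * um4_to_mm4,
       imax = (tr + det) * scale^4 * um4_to_mm4,
       centroid = c(x = xc, y = yc))
}

#' Whole-section cross-sectional geometry
#'
#' Total, endosteal and cortical areas (mm^2), their percentages, the
#' percent-bone-area variants for total/cortical/trabecularized pore area,
#' the parabolic index `Y = Ct.Ar * Es.Ar / Tt.Ar^2`, the principal
#' centroidal second moments of area Imin/Imax (mm^4) of the cortical pixel
#' region, and the polar section modulus
#' `Zpol = (Imin + Imax) / r_max` (mm^3), with `r_max` the maximal
#' centroid-to-periosteal-boundary distance.
#'
#' @param borders a [border_set()].
#' @param pores optional typed `pore_set` (column `type` holding
#'   `"cortical"`/`"trabecularized"`); untyped or absent pores contribute to
#'   the total-porosity variant only.
#' @return a one-row tibble of the cross-sectional geometry block.
#' @export
section_geometry <- function(borders, pores = NULL) {
  scale <- borders$scale_um_per_px
  a <- border_areas_px(borders)
  px_to_mm2 <- scale^2 * 1e-6
  tt <- a[["tt"]] * px_to_mm2
  es <- a[["es"]] * px_to_mm2
  ct <- a[["ct"]] * px_to_mm2
  if (es > tt) stop("internal inconsistency: Es.Ar > Tt.Ar")
  pore_mm2 <- function(sel) {
    if (is.null(pores) || nrow(pores) == 0) return(0)
    sum(pores$area_um2[sel]) * 1e-6
  }
  all_sel <- if (is.null(pores)) logical(0) else rep(TRUE, nrow(pores))
  p_tot <- pore_mm2(all_sel)
  has_type <- !is.null(pores) && "type" %in% names(pores)
  p_cort <- if (has_type) pore_mm2(pores$type == "cortical") else 0
  p_trab <- if (has_type) pore_mm2(pores$type == "trabecularized") else 0
  sm <- second_moments_mm4(borders$cortical_mask)
  dx <- (borders$total_polygon$x - sm$centroid["x"]) * scale / 1000
  dy <- (borders$total_polygon$y - sm$centroid["y"]) * scale / 1000
  r_max <- max(sqrt(dx^2 + dy^2))
  tibble::tibble(
    total_area_mm2 = tt,
    endosteal_area_mm2 = es,
    cortical_area_mm2 = ct,
    pct_cortical_area = ct / tt * 100,
    pct_endosteal_area = es / tt * 100,
    pct_bone_area_total = (ct - p_tot) / tt * 100,
    pct_bone_area_cortical = (ct - p_cort) / tt * 100,
    pct_bone_area_trabecularized = (ct - p_trab) / tt * 100,
    parabolic_index_Y = ct * es / tt^2,
    imin_mm4 = sm$imin,
    imax_mm4 = sm$imax,
    zpol_mm3 = (sm$imin + sm$imax) / r_max)
}

#' Aggregate pore morphometry for one region/type cell
#'
#' Totals (number, area), percent porosity, pore density and means of every
#' per-pore metric for a list of pores sharing a region/type context. An
#' empty pore list yields zero totals and `NA` means.
#'
#' @param pores a `pore_set` tibble (possibly zero rows).
#' @param region_area_um2 cortical area of the region, strictly positive.
#' @param total_area_um2 whole-section total area, for the percent-of-total
#'   columns (defaults to `region_area_um2`).
#' @param region,type labels recorded in the output row.
#' @return a one-row summary tibble.
#' @export
summarize_pores <- function(pores, region_area_um2, total_area_um2 = region_area_um2,
                            region = "All", type = "Total") {
  if (region_area_um2 <= 0) stop("region area must be positive")
  n <- nrow(pores)
  tot_area <- if (n) sum(pores$area_um2) else 0
  mean_or_na <- function(v) if (n) mean(v) else NA_real_
  tibble::tibble(
    region = region,
    pore_type = type,
    cortical_area_um2 = region_area_um2,
    cortical_area_mm2 = region_area_um2 * 1e-6,
    pct_cortical_area = region_area_um2 / total_area_um2 * 100,
    bone_area_um2 = region_area_um2 - tot_area,
    pct_bone_area = (region_area_um2 - tot_area) / total_area_um2 * 100,
    percent_porosity = tot_area / region_area_um2 * 100,
    total_pore_number = n,
    total_pore_area_um2 = tot_area,
    pore_density_per_um2 = n / region_area_um2,
    pore_density_per_mm2 = n / (region_area_um2 * 1e-6),
    mean_pore_area_um2 = mean_or_na(pores$area_um2),
    mean_pore_perimeter_um = mean_or_na(pores$perimeter_um),
    mean_pore_circularity = mean_or_na(pores$circularity),
    mean_pore_feret_max_um = mean_or_na(pores$feret_max_um),
    mean_pore_feret_min_um = mean_or_na(pores$feret_min_um),
    mean_pore_aspect_ratio = mean_or_na(pores$aspect_ratio),
    mean_pore_roundness = mean_or_na(pores$roundness),
    mean_pore_solidity = mean_or_na(pores$solidity))
}
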