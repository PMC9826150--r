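# Pore-type classification: the marrow cavity is converted to a Euclidean
# distance map across the cortex; a pore is "trabecularized" when its
# minimum Feret diameter is at least its minimum distance from the
# endosteum, and "cortical" otherwise. Feret and distance are both compared
# in micrometres (isotropic pixels).

#' Euclidean distance map from the endosteal (marrow) region
#'
#' Each pixel's value is the exact Euclidean distance (pixels) to the
#' nearest marrow pixel; the marrow region is the union of all endosteal
#' polygons (auxiliary holes included). Sections without a marrow cavity
#' return an infinite-distance sentinel map (every pore classifies as
#' cortical), with a message.
#'
#' @param borders a [border_set()].
#' @return an `endosteal_distance_map`: list with `distances` (matrix, px)
#'   and `scale_um_per_px`.
#' @export
endosteal_edm <- function(borders) {
  d <- dim(borders$cortical_mask$pixels)
  if (!length(borders$endosteal_polygons)) {
    message("no marrow cavity: all pores will classify as cortical")
    dist <- matrix(Inf, d[1], d[2])
  } else {
    marrow <- matrix(FALSE, d[1], d[2])
    for (p in borders$endosteal_polygons)
      marrow <- marrow | rasterize_roi(p, d)$pixels
    dist <- distance_map(marrow)
  }
  structure(list(distances = dist,
                 scale_um_per_px = borders$scale_um_per_px),
            class = "endosteal_distance_map")
}

#' Minimum endosteal distance of a pore
#'
#' Minimum distance-map value over the pore's pixels, in micrometres.
#'
#' @param pore_pixels integer vector of 1-based matrix indices (a `pixels`
#'   list-column entry of a `pore_set`).
#' @param edm an [endosteal_edm()] result.
#' @return distance in micrometres (possibly `Inf`).
#' @export
min_endosteal_distance <- function(pore_pixels, edm) {
  if (!length(pore_pixels)) stop("pore has no pixels")
  min(edm$distances[pore_pixels]) * edm$scale_um_per_px
}

#' Classify one pore by the diameter-versus-distance rule
#'
#' `trabecularized` iff the minimum Feret diameter is greater than or equal
#' to the minimum endosteal distance (equality counts as trabecularized),
#' else `cortical`.
#'
#' @param min_feret_um minimum caliper diameter (um), non-negative.
#' @param min_distance_um minimum endosteal distance (um), non-negative.
#' @return `"trabecularized"` or `"cortical"`.
#' @export
classify_pore <- function(min_feret_um, min_distance_um) {
  if (any(min_feret_um < 0) || any(min_distance_um < 0))
    stop("feret and distance must be non-negative")
  ifelse(min_feret_um >= min_distance_um, "trabecularized", "cortical")
}

#' Classify every pore of a pore set
#'
#' Adds `min_endosteal_distance_um` and `type` columns.
#'
#' @param pores a `pore_set` tibble.
#' @param edm an [endosteal_edm()] result (or a [border_set()], from which
#'   the map is computed).
#' @return the typed pore table.
#' @export
classify_pores <- function(pores, edm) {
  if (inherits(edm, "border_set")) edm <- endosteal_edm(edm)
  dist <- vapply(pores$pixels, min_endosteal_distance, numeric(1), edm = edm)
  pores$min_endosteal_distance_um <- dist
  pores$type <- ifelse(is.infinite(dist), "cortical",
                       classify_pore(pores$feret_min_um, dist))
  pores
}
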