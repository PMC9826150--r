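# Regional subdivision: rib cutaneous/pleural halves along the major (or
# minor) axis, long-bone quadrants from a starting axis rotated 45 deg and
# 90 deg, and majority-area assignment of each pore to a region through the
# rendered gray-mean mechanism.

#' Principal axis of a mask
#'
#' Area centroid and orientation of the principal (largest-eigenvalue) axis
#' of the second-moment tensor, angle in `[0, 180)` degrees measured from
#' the +x axis toward +y (screen-downward).
#'
#' @param mask a [binary_mask()] (or logical matrix).
#' @return list with `centroid` (`c(x, y)`, 0-based pixels) and
#'   `angle_deg`.
#' @export
principal_axis <- function(mask) {
  px <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  idx <- which(px)
  if (!length(idx)) stop("empty mask")
  h <- nrow(px)
  ys <- (idx - 1) %% h; xs <- (idx - 1) %/% h
  xc <- mean(xs); yc <- mean(ys)
  mxx <- mean((xs - xc)^2); myy <- mean((ys - yc)^2)
  mxy <- mean((xs - xc) * (ys - yc))
  ang <- atan2(2 * mxy, mxx - myy) / 2 * 180 / pi
  ang <- ang %% 180
  list(centroid = c(x = xc, y = yc), angle_deg = ang,
       isotropic = abs(mxx - myy) < 1e-9 * (mxx + myy) && abs(mxy) < 1e-9 * (mxx + myy))
}

#' Region partition of the cortical area
#'
#' @param region_masks named list of logical matrices, pairwise disjoint,
#'   whose union is exactly the cortical mask.
#' @param axis_used `"major"`, `"minor"` or `"horizontal"`.
#' @param centroid `c(x, y)` section centroid in pixels.
#' @param scale_um_per_px calibration.
#' @return a `region_partition`.
#' @export
region_partition <- function(region_masks, axis_used, centroid, scale_um_per_px) {
  structure(list(region_masks = region_masks,
                 region_names = names(region_masks),
                 axis_used = axis_used, centroid = centroid,
                 scale_um_per_px = scale_um_per_px),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> axis:", x$axis_used, "| regions:",
      paste(sprintf("%s (%d px)", x$region_names,
                    vapply(x$region_masks, sum, numeric(1))), collapse = ", "), "\n")
  invisible(x)
}

half_circularity <- function(px, scale) {
  # circularity of the half's outer silhouette polygon (capped 4*pi*A/P^2)
  lab <- cpp_label(px, 8L)
  counts <- tabulate(lab[lab > 0])
  poly <- cpp_trace_crack(lab, which.max(counts))
  a <- shoelace_area(poly[, 1], poly[, 2])
  p <- polygon_perimeter(poly[, 1], poly[, 2])
  min(1, 4 * pi * a / p^2)
}

#' Split a rib section into cutaneous and pleural halves
#'
#' Cortical pixels are split by the line through the centroid along the
#' chosen principal axis into two half-plane regions. The half whose outer
#' silhouette is more circular is guessed to be the pleural cortex (it
#' carries the costal groove); the caller may switch the labeling.
#'
#' @param borders a [border_set()].
#' @param axis_choice `"major"` (default) or `"minor"`.
#' @param swap_labels switch the cutaneous/pleural designation.
#' @return list with `partition` (a [region_partition()]) and
#'   `pleural_guess` (name of the half guessed pleural).
#' @export
split_rib <- function(borders, axis_choice = c("major", "minor"),
                      swap_labels = FALSE) {
  axis_choice <- match.arg(axis_choice)
  cm <- borders$cortical_mask$pixels
  ax <- principal_axis(cm)
  ang <- ax$angle_deg
  if (ax$isotropic) {
    warning("isotropic section: falling back to the horizontal axis")
    ang <- 0
  } else if (axis_choice == "minor") ang <- (ang + 90) %% 180
  theta <- ang * pi / 180
  h <- nrow(cm); w <- ncol(cm)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  # signed distance from the axis line (normal = (-sin, cos))
  s <- -(xs - ax$centroid["x"]) * sin(theta) + (ys - ax$centroid["y"]) * cos(theta)
  half1 <- cm & (s >= 0)
  half2 <- cm & (s < 0)
  c1 <- half_circularity(half1, borders$scale_um_per_px)
  c2 <- half_circularity(half2, borders$scale_um_per_px)
  pleural_first <- c1 >= c2
  if (swap_labels) pleural_first <- !pleural_first
  masks <- if (pleural_first) list(Pleural = half1, Cutaneous = half2)
           else list(Cutaneous = half1, Pleural = half2)
  part <- region_partition(masks, axis_choice, ax$centroid,
                           borders$scale_um_per_px)
  list(partition = part, pleural_guess = "Pleural",
       half_circularities = c(c1, c2))
}

#' Split a long-bone section into four anatomical quadrants
#'
#' The starting axis (horizontal through the centroid, or the principal
#' major/minor axis) is rotated by 45 deg and 90 deg: the two boundary lines
#' at starting-axis angle +/- 45 deg define four 90-degree sectors centered
#' on the starting axis and its normal. Cortical pixels are assigned by
#' half-open sector membership, so the partition is exact (disjoint and
#' exhaustive). Names map to sectors counter-clockwise from the
#' starting-axis direction.
#'
#' @param borders a [border_set()].
#' @param alignment `"image_aligned"` (horizontal starting axis),
#'   `"major_axis"` or `"minor_axis"`.
#' @param names four distinct region labels, counter-clockwise from the
#'   starting axis.
#' @return a [region_partition()].
#' @export
split_quadrants <- function(borders,
                            alignment = c("image_aligned", "major_axis", "minor_axis"),
                            names = c("Anterior", "Lateral", "Posterior", "Medial")) {
  alignment <- match.arg(alignment)
  if (length(names) != 4 || anyDuplicated(names))
    stop("names must be 4 distinct labels")
  cm <- borders$cortical_mask$pixels
  ax <- principal_axis(cm)
  theta <- switch(alignment,
    image_aligned = 0,
    major_axis = ax$angle_deg * pi / 180,
    minor_axis = (ax$angle_deg + 90) %% 180 * pi / 180)
  h <- nrow(cm); w <- ncol(cm)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  # polar angle relative to the starting axis; y points down on screen, so
  # counter-clockwise on screen is decreasing atan2 in array coordinates
  phi <- (-(atan2(ys - ax$centroid["y"], xs - ax$centroid["x"])) - theta) * 180 / pi
  sector <- floor(((phi + 45) %% 360) / 90) + 1  # half-open [theta-45, theta+45)
  masks <- lapply(1:4, function(k) cm & (sector == k))
  names(masks) <- names
  region_partition(masks, switch(alignment, image_aligned = "horizontal",
                                 major_axis = "major", minor_axis = "minor"),
                   ax$centroid, borders$scale_um_per_px)
}

#' Assign pores to regions by the rendered gray-mean rule
#'
#' Each region mask is rendered at brightness 255 and the mean value under
#' each pore's footprint is recorded per region: a pore fully inside a
#' region scores 255 there and 0 elsewhere; boundary pores score
#' proportionally to their overlap. Each pore is assigned to the arg-max
#' region (equivalent to maximal overlap-area fraction); exact ties go to
#' the first region in declared name order, with a notice. Pores with no
#' cortical overlap are flagged `"unassigned"` with a warning.
#'
#' @param pores a `pore_set` tibble.
#' @param partition a [region_partition()].
#' @return the pore table with a `region` column and a `gray_means` matrix
#'   column (one column per region).
#' @export
assign_pores <- function(pores, partition) {
  nms <- partition$region_names
  k <- length(nms)
  gm <- matrix(0, nrow(pores), k, dimnames = list(NULL, nms))
  region <- character(nrow(pores))
  tie <- FALSE
  for (i in seq_len(nrow(pores))) {
    idx <- pores$pixels[[i]]
    means <- vapply(partition$region_masks,
                    function(m) mean(m[idx]) * 255, numeric(1))
    gm[i, ] <- means
    if (all(means == 0)) {
      region[i] <- "unassigned"
    } else {
      best <- which(means == max(means))
      if (length(best) > 1) tie <- TRUE
      region[i] <- nms[best[1]]
    }
  }
  if (any(region == "unassigned"))
    warning(sum(region == "unassigned"),
            " pore(s) have no overlap with any region; flagged 'unassigned'")
  if (tie) message("exact 50/50 region tie(s) resolved to the first region in name order")
  pores$region <- region
  pores$gray_means <- gm
  pores
}
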