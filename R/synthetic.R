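# Deterministic generator of brightfield-like bone cross-sections with
# planted, fully known geometry: off-white background outside the section,
# mid-gray mineralized tissue, near-white pore lumens ringed by dark
# borders, an annular or elliptical (long-bone) or crescent (rib) cortex,
# plus additive noise and uneven illumination. Every planted pore carries
# its true area, Feret diameter, region and type label so each pipeline
# stage can be checked against ground truth.

#' Synthetic section blueprint
#'
#' Photometric defaults mimic a resin-embedded brightfield appearance:
#' off-white exterior ~245, tissue ~150, lumen ~240, pore border ~60.
#'
#' @param shape `"annulus"`, `"ellipse_ring"` or `"crescent_rib"`.
#' @param dim_px image `c(height, width)`.
#' @param center `c(x, y)` section center (default image center).
#' @param outer,inner geometry: radius for `annulus`; `c(a, b)` semi-axes
#'   for the elliptical shapes. For `crescent_rib`, `inner_offset` shifts
#'   the marrow ellipse.
#' @param inner_offset `c(dx, dy)` shift of the inner ellipse (crescent).
#' @param scale_um_per_px calibration (default 1).
#' @param pores data frame with columns `x`, `y`, `r_px` of planted circular
#'   pores, or `NULL` for the default 40-pore three-ring layout.
#' @param gray_background,gray_tissue,gray_lumen,gray_border photometrics.
#' @param noise_sd additive Gaussian noise standard deviation (gray levels).
#' @param illumination_gradient peak-to-peak amplitude of a horizontal
#'   linear illumination ramp (gray levels).
#' @param pre_cleared render exterior and marrow at absolute 0.
#' @param rng_seed integer seed controlling all randomness.
#' @return a `section_blueprint`.
#' @export
section_blueprint <- function(shape = c("annulus", "ellipse_ring", "crescent_rib"),
                              dim_px = c(850, 850), center = NULL,
                              outer = 400, inner = 180,
                              inner_offset = c(0, 0),
                              scale_um_per_px = 1,
                              pores = NULL,
                              gray_background = 245, gray_tissue = 150,
                              gray_lumen = 240, gray_border = 60,
                              noise_sd = 0, illumination_gradient = 0,
                              pre_cleared = FALSE, rng_seed = 1L) {
  shape <- match.arg(shape)
  if (is.null(center)) center <- c((dim_px[2] - 1) / 2, (dim_px[1] - 1) / 2)
  if (!(gray_border < gray_tissue && gray_tissue < gray_lumen && gray_lumen <= 255))
    stop("gray levels must satisfy border < tissue < lumen <= 255")
  structure(list(shape = shape, dim_px = dim_px, center = center,
                 outer = outer, inner = inner, inner_offset = inner_offset,
                 scale_um_per_px = scale_um_per_px, pores = pores,
                 gray_background = gray_background, gray_tissue = gray_tissue,
                 gray_lumen = gray_lumen, gray_border = gray_border,
                 noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 pre_cleared = pre_cleared, rng_seed = as.integer(rng_seed)),
            class = "section_blueprint")
}

default_pore_layout <- function(bp) {
  # three concentric rings of pores inside an annular cortex; radii drawn
  # uniformly in [27, 33] px so every pore clears the >2000 um^2 size filter
  # (at 1 um/px) and sits at least ~5 px from both cortical surfaces
  stopifnot(bp$shape == "annulus")
  ring_r <- bp$inner + (bp$outer - bp$inner) * c(0.18, 0.50, 0.82)
  counts <- c(14L, 13L, 13L)
  offs <- c(3, 16, 7) * pi / 180
  rows <- list()
  rmin <- 27; rmax <- 33
  for (k in 1:3) {
    ang <- offs[k] + 2 * pi * (seq_len(counts[k]) - 1) / counts[k]
    r <- runif(counts[k], rmin, rmax)
    rows[[k]] <- data.frame(x = bp$center[1] + ring_r[k] * cos(ang),
                            y = bp$center[2] + ring_r[k] * sin(ang),
                            r_px = r)
  }
  do.call(rbind, rows)
}

section_masks <- function(bp) {
  h <- bp$dim_px[1]; w <- bp$dim_px[2]
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  inside_ellipse <- function(cx, cy, a, b)
    ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  if (bp$shape == "annulus") {
    outer <- inside_ellipse(bp$center[1], bp$center[2], bp$outer[1], bp$outer[1])
    inner <- inside_ellipse(bp$center[1], bp$center[2], bp$inner[1], bp$inner[1])
  } else if (bp$shape == "ellipse_ring") {
    outer <- inside_ellipse(bp$center[1], bp$center[2], bp$outer[1], bp$outer[2])
    inner <- inside_ellipse(bp$center[1], bp$center[2], bp$inner[1], bp$inner[2])
  } else {
    outer <- inside_ellipse(bp$center[1], bp$center[2], bp$outer[1], bp$outer[2])
    inner <- inside_ellipse(bp$center[1] + bp$inner_offset[1],
                            bp$center[2] + bp$inner_offset[2],
                            bp$inner[1], bp$inner[2])
    inner <- inner & outer
  }
  list(outer = outer, inner = inner, cortex = outer & !inner,
       xs = xs, ys = ys)
}

# analytic minimum distance from a point to the marrow region boundary
marrow_distance <- function(bp, px, py) {
  if (bp$shape == "annulus") {
    sqrt((px - bp$center[1])^2 + (py - bp$center[2])^2) - bp$inner[1]
  } else {
    a <- bp$inner[1]; b <- bp$inner[2]
    cx <- bp$center[1] + bp$inner_offset[1]
    cy <- bp$center[2] + bp$inner_offset[2]
    vapply(seq_along(px), function(i) {
      f <- function(t) sqrt((px[i] - (cx + a * cos(t)))^2 +
                            (py[i] - (cy + b * sin(t)))^2)
      min(vapply(seq(0, 2 * pi, length.out = 720), f, numeric(1)))
    }, numeric(1))
  }
}

quadrant_name_for <- function(bp, px, py,
                              names = c("Anterior", "Lateral", "Posterior", "Medial")) {
  phi <- (-atan2(py - bp$center[2], px - bp$center[1])) * 180 / pi
  names[floor(((phi + 45) %% 360) / 90) + 1]
}

#' Generate a synthetic cross-section with ground truth
#'
#' Deterministic for a given `rng_seed`. Planted pores are circles rendered
#' as a near-white lumen ringed by a 2 px dark border; the ground-truth
#' table carries each pore's analytic geometry, its quadrant (by center
#' angle) and its type under the diameter-vs-endosteal-distance rule.
#'
#' @param bp a [section_blueprint()].
#' @return list with `image` (a `calibrated_image`), `truth` (tibble) and
#'   `blueprint`.
#' @export
generate_section <- function(bp) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(bp$rng_seed)
  sm <- section_masks(bp)
  pores <- if (is.null(bp$pores)) default_pore_layout(bp) else bp$pores
  n <- nrow(pores)
  # overlap / containment checks
  if (n > 1) {
    d <- as.matrix(dist(pores[, c("x", "y")]))
    rs <- outer(pores$r_px, pores$r_px, "+")
    diag(d) <- Inf
    bad <- which(d <= rs, arr.ind = TRUE)
    if (nrow(bad))
      stop("planted pores overlap: pairs ",
           paste(unique(apply(bad, 1, function(r) paste(sort(r), collapse = "-"))),
                 collapse = ", "))
  }
  h <- bp$dim_px[1]; w <- bp$dim_px[2]
  img <- matrix(bp$gray_tissue, h, w)
  img[!sm$cortex] <- if (bp$pre_cleared) 0 else bp$gray_background
  for (i in seq_len(n)) {
    dx <- sm$xs - pores$x[i]; dy <- sm$ys - pores$y[i]
    d2 <- dx^2 + dy^2
    ring <- d2 <= pores$r_px[i]^2 & d2 > (pores$r_px[i] - 2)^2
    lumen <- d2 <= (pores$r_px[i] - 2)^2
    if (any((ring | lumen) & !sm$cortex))
      stop("planted pore ", i, " extends outside the cortex")
    img[ring] <- bp$gray_border
    img[lumen] <- bp$gray_lumen
  }
  if (bp$illumination_gradient != 0) {
    ramp <- bp$illumination_gradient * ((sm$xs / (w - 1)) - 0.5)
    keep0 <- img == 0
    img <- img + ramp
    img[keep0] <- 0
  }
  if (bp$noise_sd > 0) {
    keep0 <- img == 0
    img <- img + matrix(rnorm(h * w, 0, bp$noise_sd), h, w)
    img[keep0] <- 0
  }
  img <- round(img); img[img < 0] <- 0; img[img > 255] <- 255
  scale <- bp$scale_um_per_px
  dist_um <- (marrow_distance(bp, pores$x, pores$y) - pores$r_px) * scale
  dist_um <- pmax(dist_um, 0)
  truth <- tibble::tibble(
    id = seq_len(n),
    x = pores$x, y = pores$y, r_px = pores$r_px,
    area_um2 = pi * (pores$r_px * scale)^2,
    feret_min_um = 2 * pores$r_px * scale,
    feret_max_um = 2 * pores$r_px * scale,
    min_endosteal_distance_um = dist_um,
    region = quadrant_name_for(bp, pores$x, pores$y),
    type = ifelse(2 * pores$r_px * scale >= dist_um, "trabecularized", "cortical"))
  list(image = calibrated_image(img, scale, "GRAY"),
       truth = truth, blueprint = bp)
}

#' Analytic shape fixtures for metric unit tests
#'
#' Rasterized elementary shapes with their closed-form measurements.
#'
#' @param kind `"disk"`, `"square"`, `"rectangle"`, `"ellipse"` or
#'   `"spiky_blob"`.
#' @param params named list: `r` (disk), `side` (square), `w`/`h`
#'   (rectangle), `a`/`b` (ellipse), `r`/`spikes`/`amplitude` (spiky blob).
#' @param seed RNG seed (spiky blob phase).
#' @param pad margin in pixels around the shape.
#' @param scale_um_per_px calibration.
#' @return list with `mask` (a [binary_mask()]) and `analytic` (one-row
#'   tibble of closed-form area/perimeter/Feret/second-moment values where
#'   defined).
#' @export
generate_shape_fixture <- function(kind = c("disk", "square", "rectangle",
                                            "ellipse", "spiky_blob"),
                                   params = list(), seed = 1L, pad = 4,
                                   scale_um_per_px = 1) {
  kind <- match.arg(kind)
  p <- params
  mk <- function(h, w, f) {
    xs <- matrix(rep(0:(w - 1), each = h), h, w)
    ys <- matrix(rep(0:(h - 1), times = w), h, w)
    f(xs, ys)
  }
  if (kind == "disk") {
    r <- p$r %||% 50
    n <- ceiling(2 * (r + pad)) + 1
    cx <- (n - 1) / 2
    mask <- mk(n, n, function(xs, ys) (xs - cx)^2 + (ys - cx)^2 <= r^2)
    analytic <- tibble::tibble(area = pi * r^2, perimeter = 2 * pi * r,
                               feret_max = 2 * r, feret_min = 2 * r,
                               imin = pi * r^4 / 4, imax = pi * r^4 / 4)
  } else if (kind == "square") {
    s <- p$side %||% 10
    mask <- mk(s + 2 * pad, s + 2 * pad,
               function(xs, ys) xs >= pad & xs < pad + s & ys >= pad & ys < pad + s)
    analytic <- tibble::tibble(area = s^2, perimeter = 4 * s,
                               feret_max = s * sqrt(2), feret_min = s,
                               imin = s^4 / 12, imax = s^4 / 12)
  } else if (kind == "rectangle") {
    wd <- p$w %||% 200; ht <- p$h %||% 100
    mask <- mk(ht + 2 * pad, wd + 2 * pad,
               function(xs, ys) xs >= pad & xs < pad + wd & ys >= pad & ys < pad + ht)
    analytic <- tibble::tibble(area = wd * ht, perimeter = 2 * (wd + ht),
                               feret_max = sqrt(wd^2 + ht^2), feret_min = min(wd, ht),
                               imin = wd * min(wd, ht)^3 / 12,
                               imax = ht * max(wd, ht)^3 / 12)
  } else if (kind == "ellipse") {
    a <- p$a %||% 60; b <- p$b %||% 30
    n <- ceiling(2 * (max(a, b) + pad)) + 1
    cx <- (n - 1) / 2
    mask <- mk(n, n, function(xs, ys) ((xs - cx) / a)^2 + ((ys - cx) / b)^2 <= 1)
    analytic <- tibble::tibble(area = pi * a * b, perimeter = NA_real_,
                               feret_max = 2 * a, feret_min = 2 * b,
                               imin = pi * a * b^3 / 4, imax = pi * b * a^3 / 4)
  } else {
    r <- p$r %||% 40; spikes <- p$spikes %||% 9; amp <- p$amplitude %||% 6
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    phase <- runif(1, 0, 2 * pi)
    n <- ceiling(2 * (r + amp + pad)) + 1
    cx <- (n - 1) / 2
    mask <- mk(n, n, function(xs, ys) {
      th <- atan2(ys - cx, xs - cx)
      rad <- r + amp * sin(spikes * th + phase)
      (xs - cx)^2 + (ys - cx)^2 <= rad^2
    })
    analytic <- tibble::tibble(area = NA_real_, perimeter = NA_real_,
                               feret_max = NA_real_, feret_min = NA_real_,
                               imin = NA_real_, imax = NA_real_)
  }
  list(mask = binary_mask(mask, scale_um_per_px), analytic = analytic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
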