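# Optional enhancement sequence: contrast operations, illumination
# correction, smoothing and channel splitting, composable as an ordered,
# logged pipeline over one image or a folder. Every op maps [0, 255] into
# [0, 255], is deterministic, and uses reflective boundaries for
# convolutions (avoids dark rims at a cleared-black section edge).

clamp255 <- function(px) { px[px < 0] <- 0; px[px > 255] <- 255; px }

apply_gray_op <- function(image, f) {
  px <- image$pixels
  if (length(dim(px)) == 3) {
    for (c in 1:3) px[, , c] <- f(px[, , c])
  } else px <- f(px)
  calibrated_image(px, image$scale_um_per_px, image$channel_tag)
}

#' Auto-optimize brightness/contrast
#'
#' Linear rescale so that `saturated_fraction` of pixels saturates at 0/255
#' (half at each end); with fraction 0 the histogram minimum maps to 0 and
#' the maximum to 255. Constant images are returned unchanged.
#'
#' @param image a `calibrated_image`.
#' @param saturated_fraction fraction in `[0, 1)` of pixels allowed to
#'   saturate (default 0).
#' @return the rescaled image.
#' @export
auto_contrast <- function(image, saturated_fraction = 0) {
  if (saturated_fraction < 0 || saturated_fraction >= 1)
    stop("saturated_fraction must be in [0, 1)")
  apply_gray_op(image, function(px) {
    q <- if (saturated_fraction == 0) range(px) else
      stats::quantile(px, c(saturated_fraction / 2, 1 - saturated_fraction / 2), names = FALSE)
    if (q[2] <= q[1]) return(px)
    clamp255(round((px - q[1]) * 255 / (q[2] - q[1])))
  })
}

#' Histogram normalization or equalization
#'
#' `normalize` linearly stretches the histogram to `[0, 255]`; `equalize`
#' applies the cumulative-histogram mapping, flattening the gray-level
#' distribution. Constant images are returned unchanged.
#'
#' @param image a grayscale `calibrated_image`.
#' @param mode `"normalize"` or `"equalize"`.
#' @return the remapped image.
#' @export
equalize_or_normalize <- function(image, mode = c("normalize", "equalize")) {
  mode <- match.arg(mode)
  apply_gray_op(image, function(px) {
    r <- range(px)
    if (r[1] == r[2]) return(px)
    if (mode == "normalize") {
      clamp255(round((px - r[1]) * 255 / (r[2] - r[1])))
    } else {
      h <- tabulate(as.integer(px) + 1L, nbins = 256L)
      cdf <- cumsum(h) / length(px)
      matrix(round(255 * cdf[as.integer(px) + 1L]), nrow(px), ncol(px))
    }
  })
}

#' Contrast-limited local (adaptive) histogram equalization
#'
#' Equalizes contrast per tile of `blocksize_px` pixels with a clip limit on
#' histogram bins, interpolating mappings bilinearly between tile centers.
#' The global mean brightness stays within about 10% of the input.
#'
#' @param image a grayscale `calibrated_image`.
#' @param blocksize_px tile edge length, at least 3.
#' @param clip positive clip factor relative to the uniform bin height
#'   (default 2.5).
#' @return the locally equalized image.
#' @export
local_contrast <- function(image, blocksize_px = 127, clip = 2.5) {
  if (blocksize_px < 3) stop("blocksize_px must be at least 3")
  apply_gray_op(image, function(px) {
    h <- nrow(px); w <- ncol(px)
    if (blocksize_px > max(h, w)) stop("blocksize larger than image")
    if (diff(range(px)) == 0) return(px)
    nty <- max(1L, ceiling(h / blocksize_px))
    ntx <- max(1L, ceiling(w / blocksize_px))
    ye <- round(seq(0, h, length.out = nty + 1))
    xe <- round(seq(0, w, length.out = ntx + 1))
    yc <- (head(ye, -1) + tail(ye, -1)) / 2
    xc <- (head(xe, -1) + tail(xe, -1)) / 2
    maps <- array(0, dim = c(nty, ntx, 256))
    for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
      tile <- px[(ye[ty] + 1):ye[ty + 1], (xe[tx] + 1):xe[tx + 1]]
      hist <- tabulate(as.integer(tile) + 1L, nbins = 256L)
      limit <- clip * length(tile) / 256
      excess <- sum(pmax(hist - limit, 0))
      hist <- pmin(hist, limit) + excess / 256
      cdf <- cumsum(hist) / sum(hist)
      maps[ty, tx, ] <- 255 * cdf
    }
    # bilinear interpolation of per-tile mappings
    if (nty == 1) { yi <- rep(1L, h); fy <- rep(0, h) } else {
      yi <- findInterval(seq_len(h) - 0.5, yc, all.inside = TRUE)
      fy <- pmin(1, pmax(0, ((seq_len(h) - 0.5) - yc[yi]) / pmax(1e-9, yc[yi + 1] - yc[yi])))
    }
    if (ntx == 1) { xi <- rep(1L, w); fx <- rep(0, w) } else {
      xi <- findInterval(seq_len(w) - 0.5, xc, all.inside = TRUE)
      fx <- pmin(1, pmax(0, ((seq_len(w) - 0.5) - xc[xi]) / pmax(1e-9, xc[xi + 1] - xc[xi])))
    }
    out <- matrix(0, h, w)
    TY <- rep(yi, times = w); TX <- rep(xi, each = h)
    FY <- rep(fy, times = w); FX <- rep(fx, each = h)
    V <- as.integer(px) + 1L
    v00 <- maps[cbind(TY, TX, V)]
    v01 <- maps[cbind(TY, pmin(TX + 1L, ntx), V)]
    v10 <- maps[cbind(pmin(TY + 1L, nty), TX, V)]
    v11 <- maps[cbind(pmin(TY + 1L, nty), pmin(TX + 1L, ntx), V)]
    out[] <- (1 - FY) * ((1 - FX) * v00 + FX * v01) + FY * ((1 - FX) * v10 + FX * v11)
    clamp255(round(out))
  })
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

#' Highpass filter (Gaussian-subtraction illumination correction)
#'
#' Subtracts a Gaussian-blurred version of the image (sigma derived from the
#' large-structure size) and re-centers at 128, flattening slowly varying
#' illumination while preserving fine detail.
#'
#' @param image a grayscale `calibrated_image`.
#' @param large_structure_px size of the structures to suppress; the blur
#'   sigma is `large_structure_px / 2`.
#' @return the filtered image.
#' @export
highpass <- function(image, large_structure_px) {
  if (large_structure_px <= 0) stop("large_structure_px must be positive")
  k <- gaussian_kernel(large_structure_px / 2)
  apply_gray_op(image, function(px) {
    clamp255(round(px - cpp_sep_conv(px, k) + 128))
  })
}

#' Rolling-ball / paraboloid background subtraction
#'
#' Estimates the background as a grayscale opening with a ball-shaped (or
#' paraboloid) structuring surface of the given radius rolled under the
#' intensity surface, and subtracts it. With `light_background = TRUE` the
#' ball is rolled over the surface instead (background bright, structures
#' dark).
#'
#' @param image a grayscale `calibrated_image`.
#' @param ball_radius_px structuring radius, at least 1.
#' @param method `"ball"` or `"paraboloid"`.
#' @param light_background roll over rather than under the surface.
#' @return the background-subtracted image.
#' @export
subtract_background <- function(image, ball_radius_px, method = c("ball", "paraboloid"),
                                light_background = FALSE) {
  method <- match.arg(method)
  if (ball_radius_px < 1) stop("ball_radius_px must be at least 1")
  apply_gray_op(image, function(px) {
    work <- if (light_background) 255 - px else px
    bg <- if (method == "ball") {
      cpp_gray_ball(cpp_gray_ball(work, ball_radius_px, 0L), ball_radius_px, 1L)
    } else {
      # paraboloid: same opening with a parabolic height profile approximated
      # by a ball of twice the radius (flatter apex)
      cpp_gray_ball(cpp_gray_ball(work, 2 * ball_radius_px, 0L), 2 * ball_radius_px, 1L)
    }
    out <- clamp255(round(work - bg))
    if (light_background) 255 - out else out
  })
}

#' Gaussian smoothing
#'
#' Convolution with a normalized separable Gaussian kernel, reflective
#' boundary; the global mean is preserved to within a fraction of a gray
#' level.
#'
#' @param image a `calibrated_image`.
#' @param sigma_px positive standard deviation in pixels.
#' @return the smoothed image.
#' @export
gaussian_smooth <- function(image, sigma_px) {
  if (sigma_px <= 0) stop("sigma_px must be positive")
  k <- gaussian_kernel(sigma_px)
  apply_gray_op(image, function(px) clamp255(cpp_sep_conv(px, k)))
}

#' Split an RGB image into channels
#'
#' @param image an RGB `calibrated_image`.
#' @param channels which channels to extract (default all four tags).
#' @return named list of `calibrated_image`.
#' @export
split_channels <- function(image, channels = c("RGB", "RED", "GREEN", "BLUE")) {
  stats::setNames(lapply(channels, function(ch) extract_channel(image, ch)), channels)
}

#' Preprocessing step descriptor
#'
#' @param op_name one of `auto_contrast`, `normalize`, `equalize`,
#'   `local_contrast`, `highpass`, `subtract_background`, `gaussian_smooth`,
#'   `split_channels`.
#' @param ... op parameters, validated at execution.
#' @return a `preprocess_step`.
#' @export
preprocess_step <- function(op_name, ...) {
  op_name <- match.arg(op_name, c("auto_contrast", "normalize", "equalize",
                                  "local_contrast", "highpass",
                                  "subtract_background", "gaussian_smooth",
                                  "split_channels"))
  structure(list(op_name = op_name, params = list(...)), class = "preprocess_step")
}

apply_step <- function(image, step) {
  p <- step$params
  switch(step$op_name,
    auto_contrast = do.call(auto_contrast, c(list(image), p)),
    normalize = equalize_or_normalize(image, "normalize"),
    equalize = equalize_or_normalize(image, "equalize"),
    local_contrast = do.call(local_contrast, c(list(image), p)),
    highpass = do.call(highpass, c(list(image), p)),
    subtract_background = do.call(subtract_background, c(list(image), p)),
    gaussian_smooth = do.call(gaussian_smooth, c(list(image), p)),
    split_channels = do.call(split_channels, c(list(image), p)))
}

format_step <- function(step) {
  if (length(step$params) == 0) return(step$op_name)
  paste0(step$op_name, "(",
         paste(names(step$params), unlist(step$params), sep = "=", collapse = ", "), ")")
}

#' Run an ordered preprocessing sequence
#'
#' Applies the steps in the listed order to a single image or to every TIFF
#' in a folder, writing per-image output folders with the processed image(s)
#' and a text log of the executed operations. A failing step aborts that
#' image with a logged reason and the batch continues.
#'
#' @param input a `calibrated_image`, a TIFF path, or a directory of TIFFs.
#' @param steps list of [preprocess_step()].
#' @param output_dir where to write batch outputs (required for path input).
#' @param scale_um_per_px calibration used when reading from disk.
#' @return for in-memory input, a list with `image` (or `channels`) and
#'   `log`; for disk input, the output directory (invisibly).
#' @export
run_sequence <- function(input, steps, output_dir = NULL, scale_um_per_px = 1) {
  run_one <- function(image) {
    log <- character(0)
    out <- image
    for (s in steps) {
      out <- apply_step(out, s)
      log <- c(log, format_step(s))
      if (is.list(out) && !inherits(out, "calibrated_image")) break  # split_channels ends the chain
    }
    list(result = out, log = log)
  }
  if (inherits(input, "calibrated_image")) {
    r <- run_one(input)
    if (inherits(r$result, "calibrated_image"))
      return(list(image = r$result, log = r$log))
    return(list(channels = r$result, log = r$log))
  }
  if (!file.exists(input)) stop("no such file or directory: ", input)
  if (is.null(output_dir)) stop("output_dir is required for file input")
  files <- if (dir.exists(input))
    list.files(input, pattern = "\\.tiff?$", ignore.case = TRUE, full.names = TRUE)
  else input
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in files) {
    name <- tools::file_path_sans_ext(basename(f))
    odir <- file.path(output_dir, name)
    dir.create(odir, showWarnings = FALSE)
    res <- tryCatch({
      img <- read_image(f, scale_um_per_px,
                        channel = if (length(dim(read_tiff(f))) == 3) "RGB" else "GRAY")
      r <- run_one(img)
      if (inherits(r$result, "calibrated_image")) {
        write_image(r$result, file.path(odir, paste0(name, "_processed.tif")))
      } else {
        for (ch in names(r$result))
          write_image(r$result[[ch]], file.path(odir, paste0(name, "_", ch, ".tif")))
      }
      r$log
    }, error = function(e) c("ERROR: ", conditionMessage(e)))
    writeLines(res, file.path(odir, paste0(name, "_preprocess_log.txt")))
  }
  invisible(output_dir)
}
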