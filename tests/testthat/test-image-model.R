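# Core data model, TIFF and ImageJ ROI interop, rasterization.

test_that("calibrated images validate their invariants and expose physical size", {
  img <- calibrated_image(matrix(120, 10, 20), 2.5)
  expect_equal(physical_width_um(img), 20 * 2.5)
  expect_error(calibrated_image(matrix(120, 5, 5), 0), "positive")
  expect_error(calibrated_image(matrix(-3, 5, 5), 1), "\\[0, 255\\]")
  expect_error(calibrated_image(matrix(300, 5, 5), 1), "\\[0, 255\\]")
})

test_that("channel extraction: unweighted mean gray, identity on gray images", {
  a <- array(0, c(4, 4, 3))
  a[, , 1] <- 30; a[, , 2] <- 60; a[, , 3] <- 90
  rgb <- calibrated_image(a, 1)
  expect_true(all(extract_channel(rgb, "GRAY")$pixels == 60))
  # constant r=g=b image converts to the same constant
  b <- array(120, c(4, 4, 3))
  expect_true(all(extract_channel(calibrated_image(b, 1), "GRAY")$pixels == 120))
  # rounding is half-up: (1+2+2)/3 = 1.67 -> 2
  cpx <- array(c(1, 2, 2), c(1, 1, 3))
  expect_equal(as.numeric(extract_channel(calibrated_image(cpx, 1), "GRAY")$pixels), 2)
  g <- calibrated_image(matrix(7, 3, 3), 1)
  expect_identical(extract_channel(g, "GRAY"), g)
})

test_that("TIFF round trip preserves gray and RGB pixels; channels extract on read", {
  set.seed(11)
  g <- matrix(sample(0:255, 100 * 100, TRUE), 100, 100)
  tf <- tempfile(fileext = ".tif")
  write_tiff(g, tf)
  expect_equal(read_tiff(tf), g, ignore_attr = TRUE)
  a <- array(sample(0:255, 40 * 30 * 3, TRUE), c(40, 30, 3))
  ta <- tempfile(fileext = ".tif")
  write_tiff(a, ta)
  expect_equal(read_tiff(ta), a, ignore_attr = TRUE)
  img <- read_image(ta, 1.0, "GRAY")
  expect_equal(dim(img$pixels), c(40, 30))
  expect_equal(img$pixels, floor((a[, , 1] + a[, , 2] + a[, , 3]) / 3 + 0.5),
               ignore_attr = TRUE)
  expect_error(read_image(tempfile(), 1), "no such file")
  expect_error(read_image(ta, -1), "positive")
})

test_that("our TIFFs are readable by an independent reader (tifffile)", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  g <- matrix(sample(0:255, 30 * 20, TRUE), 30, 20)
  tf <- tempfile(fileext = ".tif")
  write_tiff(g, tf)
  out <- suppressWarnings(system2("python",
    c("-c", shQuote(paste0(
      "import tifffile; a = tifffile.imread('", tf,
      "'); print(a.shape[0], a.shape[1], int(a.sum()))"))),
    stdout = TRUE, stderr = TRUE))
  skip_if(length(out) == 0 || !grepl("^[0-9]+ [0-9]+ [0-9]+$", out[length(out)]),
          "tifffile unavailable")
  expect_equal(out[length(out)], paste(30, 20, sum(g)))
})

test_that("ROI archive round trip is lossless for coordinates and names", {
  set.seed(21)
  rois <- replicate(50, random_polygon(), simplify = FALSE)
  rois[[3]]$closed <- FALSE
  tf <- tempfile(fileext = ".zip")
  write_roi_archive(rois, tf)
  back <- read_roi_archive(tf)
  expect_length(back, 50)
  for (i in seq_along(rois)) {
    expect_identical(back[[i]]$x, rois[[i]]$x)
    expect_identical(back[[i]]$y, rois[[i]]$y)
    expect_identical(back[[i]]$name, rois[[i]]$name)
    expect_identical(back[[i]]$closed, rois[[i]]$closed)
  }
})

test_that("empty archives and numeric-name archives round-trip", {
  tf <- tempfile(fileext = ".zip")
  write_roi_archive(list(), tf)
  expect_identical(read_roi_archive(tf), list())
  rois <- lapply(1:500, function(i)
    roi_polygon(c(0, i %% 40 + 1, 3), c(0, 2, i %% 17 + 3), name = sprintf("%03d", i)))
  tf2 <- tempfile(fileext = ".zip")
  write_roi_archive(rois, tf2)
  back <- read_roi_archive(tf2)
  expect_identical(vapply(back, `[[`, "", "name"), sprintf("%03d", 1:500))
})

test_that("an independently encoded freehand record decodes with vertex order intact", {
  # hand-built ImageJ ROI record: freehand (type 7), 5 integer vertices,
  # bounding box top=2 left=3, no header2 (no sub-pixel data)
  u16 <- function(x) as.raw(c(x %/% 256, x %% 256))
  xs <- c(3, 7, 9, 6, 4); ys <- c(2, 2, 5, 9, 6)
  rec <- c(charToRaw("Iout"), u16(218),
           as.raw(c(7, 0)),
           u16(2), u16(3), u16(10), u16(10),
           u16(5), raw(16), u16(0), raw(4), raw(8), u16(0), u16(0),
           raw(2), u16(0), raw(4), raw(4),
           unlist(lapply(xs - 3, u16)), unlist(lapply(ys - 2, u16)))
  tf <- tempfile(fileext = ".roi")
  writeBin(rec, tf)
  got <- read_roi_archive(tf)[[1]]
  expect_equal(got$x, xs)
  expect_equal(got$y, ys)
  expect_true(got$closed)
})

test_that("unsupported ROI record types are rejected with a clear error", {
  u16 <- function(x) as.raw(c(x %/% 256, x %% 256))
  rec <- c(charToRaw("Iout"), u16(218), as.raw(c(3, 0)), raw(56))  # line type
  tf <- tempfile(fileext = ".roi")
  writeBin(rec, tf)
  expect_error(read_roi_archive(tf), "unsupported ROI record type 3")
})

test_that("rasterization matches the brute-force even-odd oracle", {
  sq <- roi_polygon(c(0, 9, 9, 0), c(0, 0, 9, 9))
  m <- rasterize_roi(sq, c(12, 12))
  expect_equal(sum(m$pixels), 100)
  expect_identical(m$pixels, oracle_rasterize(sq$x, sq$y, 12, 12))
  set.seed(31)
  for (i in 1:10) {
    p <- random_polygon()
    m1 <- rasterize_roi(p, c(110, 110))
    expect_identical(m1$pixels, oracle_rasterize(p$x, p$y, 110, 110))
    # determinism
    expect_identical(rasterize_roi(p, c(110, 110))$pixels, m1$pixels)
  }
  # triangle fully outside the image
  tri <- roi_polygon(c(200, 220, 210), c(200, 200, 220))
  expect_equal(sum(rasterize_roi(tri, c(50, 50))$pixels), 0)
  expect_error(rasterize_roi(roi_polygon(1:3, 1:3, closed = FALSE), c(10, 10)),
               "open polygon")
})

test_that("rasterize(trace(mask)) reproduces 4-connected hole-free masks", {
  set.seed(41)
  for (i in 1:15) {
    m <- random_blob_mask()
    lab <- poremorph:::cpp_label(m, 4L)
    counts <- tabulate(lab[lab > 0])
    comp <- poremorph:::fill_holes(lab == which.max(counts), 4)
    p <- trace_boundary(comp, 1L, connectivity = 4)
    expect_equal(shoelace_area(p$x, p$y), sum(comp))
    expect_identical(rasterize_roi(p, dim(comp))$pixels, comp)
  }
})
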