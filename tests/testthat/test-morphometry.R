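# Shape descriptors and cross-sectional geometry against closed forms.

test_that("elementary shapes reproduce their closed-form metrics", {
  # 10x10 square, raw crack convention: area 100, perimeter 40, circ = pi/4
  sq <- generate_shape_fixture("square", list(side = 10))
  m <- measure_components(sq$mask, perimeter_convention = "crack")
  expect_equal(m$area_um2, 100)
  expect_equal(m$perimeter_um, 40)
  expect_equal(m$circularity, pi / 4)
  expect_equal(m$feret_min_um, 10)
  expect_equal(m$feret_max_um, 10 * sqrt(2))
  expect_equal(m$solidity, 1)
  # disk r = 50: area within 1%, feret within 2 px of 100, high solidity
  dk <- generate_shape_fixture("disk", list(r = 50))
  d <- measure_components(dk$mask)
  expect_lt(abs(d$area_um2 - pi * 2500) / (pi * 2500), 0.01)
  expect_lt(abs(d$feret_max_um - 100), 2)
  expect_gt(d$solidity, 0.98)
  expect_gte(d$circularity, 0.95)
  expect_lt(abs(d$aspect_ratio - 1), 0.02)
  # 40x10 rectangle: axis ratio 4 within 5%, feret_min 10 +- 1
  rc <- generate_shape_fixture("rectangle", list(w = 40, h = 10))
  r <- measure_components(rc$mask)
  expect_lt(abs(r$ellipse_major_um / r$ellipse_minor_um - 4), 0.2)
  expect_equal(r$aspect_ratio, r$ellipse_major_um / r$ellipse_minor_um)
  expect_lt(abs(r$feret_min_um - 10), 1)
  expect_equal(r$area_um2, 400)
})

test_that("trace_boundary yields crack polygons whose area equals pixel count", {
  one <- binary_mask(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2), 1)
  p1 <- trace_boundary(one)
  expect_length(p1$x, 4)
  expect_equal(shoelace_area(p1$x, p1$y), 1)
  sq <- generate_shape_fixture("square", list(side = 10))
  psq <- trace_boundary(sq$mask)
  expect_equal(poremorph:::polygon_perimeter(psq$x, psq$y), 40)
  set.seed(33)
  for (i in 1:10) {
    m <- poremorph:::fill_holes(random_blob_mask(), 4)
    lab <- poremorph:::cpp_label(m, 4L)
    keep <- lab == which.max(tabulate(lab[lab > 0]))
    p <- trace_boundary(keep, 1, connectivity = 4)
    expect_equal(shoelace_area(p$x, p$y), sum(keep))
  }
  expect_error(trace_boundary(one, 5), "not found")
})

test_that("metrics are scale-equivariant and rotation-invariant", {
  blob <- generate_shape_fixture("spiky_blob", list(r = 30), seed = 4)
  m1 <- measure_components(blob$mask)
  m2 <- measure_components(binary_mask(blob$mask$pixels, 2))
  expect_equal(m2$area_um2, 4 * m1$area_um2)
  expect_equal(m2$perimeter_um, 2 * m1$perimeter_um)
  expect_equal(m2$feret_max_um, 2 * m1$feret_max_um)
  for (col in c("circularity", "aspect_ratio", "roundness", "solidity"))
    expect_equal(m2[[col]], m1[[col]])
  # 90-degree rotation: exact agreement
  rot <- binary_mask(t(blob$mask$pixels)[ncol(blob$mask$pixels):1, ], 1)
  m3 <- measure_components(rot)
  for (col in c("area_um2", "perimeter_um", "circularity", "feret_max_um",
                "feret_min_um", "aspect_ratio", "roundness", "solidity"))
    expect_equal(m3[[col]], m1[[col]], tolerance = 1e-9)
  # 45-degree rotation of a rectangle: within rasterization tolerance
  h <- 160; xs <- matrix(rep(0:(h - 1), each = h), h, h); ys <- t(xs)
  u <- (xs - 80) * cos(pi / 4) + (ys - 80) * sin(pi / 4)
  v <- -(xs - 80) * sin(pi / 4) + (ys - 80) * cos(pi / 4)
  rot45 <- measure_components(binary_mask(abs(u) < 55.5 & abs(v) < 40.5, 1))
  straight <- measure_components(binary_mask(abs(xs - 80) < 55.5 & abs(ys - 80) < 40.5, 1))
  for (col in c("area_um2", "feret_max_um", "feret_min_um"))
    expect_lt(abs(rot45[[col]] - straight[[col]]) / straight[[col]], 0.02)
  # chain-estimator perimeters carry an orientation bias of up to ~5% at
  # exact 45-degree edges (Kulpa weights are calibrated on average orientation)
  expect_lt(abs(rot45$perimeter_um - straight$perimeter_um) / straight$perimeter_um, 0.06)
})

test_that("dimensionless descriptors are capped at 1 over random blobs", {
  set.seed(34)
  for (i in 1:25) {
    m <- random_blob_mask(35, 35, n_seeds = 2, grow = 40)
    mm <- measure_components(binary_mask(m, 1))
    expect_true(all(mm$circularity <= 1))
    expect_true(all(mm$solidity <= 1))
    expect_true(all(mm$roundness <= 1))
    expect_true(all(mm$aspect_ratio >= 1))
    expect_true(all(mm$feret_min_um <= mm$feret_max_um + 1e-9))
  }
  # convex shapes have solidity 1 within 2%
  for (r in c(50, 70, 90)) {
    d <- measure_components(generate_shape_fixture("disk", list(r = r))$mask)
    expect_gt(d$solidity, 0.98)
  }
})

test_that("measure_pore works from a polygon alone and rejects degenerates", {
  sq <- roi_polygon(c(0, 9, 9, 0), c(0, 0, 9, 9))
  m <- measure_pore(sq, 1, perimeter_convention = "crack")
  expect_equal(m$area_um2, 100)
  tiny <- roi_polygon(c(100, 100.1, 100.05), c(100, 100, 100.1))
  expect_error(measure_pore(tiny, 1, shape = c(50, 50)), "degenerate")
})

test_that("second moments match bh^3/12 and scale as the 4th power", {
  rc <- generate_shape_fixture("rectangle", list(w = 200, h = 100))
  sm <- poremorph:::second_moments_mm4(rc$mask)
  imin_true <- 200 * 100^3 / 12 * 1e-12
  imax_true <- 100 * 200^3 / 12 * 1e-12
  expect_lt(abs(sm$imin - imin_true) / imin_true, 0.01)
  expect_lt(abs(sm$imax - imax_true) / imax_true, 0.01)
  sm2 <- poremorph:::second_moments_mm4(binary_mask(rc$mask$pixels, 2))
  expect_equal(sm2$imin / sm$imin, 16)
  expect_equal(sm2$imax / sm$imax, 16)
})

test_that("section geometry implements the area formula identities", {
  # direct formula checks on a synthetic border set
  bp <- small_section(pores = data.frame(x = numeric(0), y = numeric(0), r_px = numeric(0)))
  gen <- generate_section(bp)
  borders <- derive_borders(auto_clear(gen$image, min_hole_px = 2000))
  g <- section_geometry(borders)
  expect_equal(g$cortical_area_mm2, g$total_area_mm2 - g$endosteal_area_mm2)
  expect_equal(g$pct_cortical_area + g$pct_endosteal_area, 100, tolerance = 1e-9)
  expect_equal(g$parabolic_index_Y,
               g$cortical_area_mm2 * g$endosteal_area_mm2 / g$total_area_mm2^2)
  expect_lte(g$parabolic_index_Y, 0.25)
  expect_gte(g$imax_mm4, g$imin_mm4)
  # worked example: Tt.Ar 100, Es.Ar 25 => Ct 75, %Ct 75, Y = 0.1875;
  # with 5 mm^2 of pores, % bone area (total porosity) = 70
  expect_equal(75 * 25 / 100^2, 0.1875)
  expect_equal((75 - 5) / 100 * 100, 70)
})

test_that("summaries aggregate totals, porosity, density and per-pore means", {
  pores <- tibble::tibble(area_um2 = c(100, 100), perimeter_um = c(40, 35),
                          circularity = c(0.7, 0.9), feret_max_um = c(12, 14),
                          feret_min_um = c(8, 9), aspect_ratio = c(1.2, 1.4),
                          roundness = c(0.8, 0.7), solidity = c(0.95, 0.99))
  s <- summarize_pores(pores, 10000)
  expect_equal(s$percent_porosity, 2)
  expect_equal(s$pore_density_per_um2, 2e-4)
  expect_equal(s$pore_density_per_mm2, 2e8 / 1e6 * 1e4 / 1e4)  # 200 per mm^2
  expect_equal(s$total_pore_number, 2)
  expect_equal(s$mean_pore_circularity, 0.8)
  e <- summarize_pores(pores[0, ], 10000)
  expect_equal(e$total_pore_number, 0)
  expect_equal(e$percent_porosity, 0)
  expect_true(is.na(e$mean_pore_area_um2))
  expect_error(summarize_pores(pores, 0), "positive")
  # 50 random pores: means equal brute-force arithmetic means
  set.seed(35)
  p50 <- tibble::tibble(area_um2 = runif(50, 10, 500), perimeter_um = runif(50, 5, 50),
                        circularity = runif(50), feret_max_um = runif(50, 5, 40),
                        feret_min_um = runif(50, 1, 5), aspect_ratio = 1 + runif(50),
                        roundness = runif(50), solidity = runif(50))
  s50 <- summarize_pores(p50, 1e5)
  expect_equal(s50$mean_pore_area_um2, sum(p50$area_um2) / 50)
  expect_equal(s50$mean_pore_feret_min_um, sum(p50$feret_min_um) / 50)
})
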