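# Pore segmentation: thresholds, Phansalkar, morphology, filtering.

test_that("lumen and border thresholds match pixelwise oracles inside the cortex", {
  set.seed(23)
  g <- matrix(sample(0:255, 900, TRUE), 30, 30)
  g[1:5, ] <- 0  # cleared strip
  img <- calibrated_image(g, 1)
  m <- threshold_lumens(img, 128)
  expect_identical(m$pixels, g > 128 & g > 0)
  expect_equal(sum(threshold_lumens(img, 255)$pixels), 0)
  mb <- threshold_borders(img, 60)
  expect_identical(mb$pixels, g > 0 & g < 60)
  expect_equal(sum(threshold_borders(img, 0)$pixels), 0)
  # cleared-black background never selected at any border threshold
  expect_false(any(threshold_borders(img, 255)$pixels[1:5, ]))
  expect_error(threshold_lumens(img, 300), "\\[0, 255\\]")
  # monotonicity: lowering the lumen threshold never removes pixels
  hi <- threshold_lumens(img, 180)$pixels
  lo <- threshold_lumens(img, 120)$pixels
  expect_true(all(lo[hi]))
})

test_that("planted dark rings are picked up by the border threshold", {
  bp <- small_section()
  gen <- generate_section(bp)
  img <- gen$image
  cm <- binary_mask(poremorph:::section_masks(bp)$cortex, 1)
  mb <- threshold_borders(img, 100, cm)
  # ring pixels only: value 60, all within 2 px of a planted pore edge
  idx <- which(mb$pixels)
  expect_true(length(idx) > 0)
  expect_true(all(img$pixels[idx] == 60))
})

test_that("Phansalkar threshold equals brute-force evaluation of the formula", {
  set.seed(24)
  g <- matrix(sample(0:255, 81, TRUE), 9, 9)
  img <- calibrated_image(g, 1)
  got <- threshold_phansalkar(img, threshold_spec("phansalkar", phansalkar_radius_px = 3))
  expect_identical(got$pixels, oracle_phansalkar(g, 3))
  # constant image: uniform neighborhood, never a mixed mask
  const <- threshold_phansalkar(calibrated_image(matrix(128, 12, 12), 1),
                                threshold_spec("phansalkar"))
  expect_true(sum(const$pixels) %in% c(0, 144))
  # bright disk on darker textured tissue comes out as one component
  set.seed(25)
  tex <- matrix(pmin(255, pmax(0, round(120 + rnorm(1600, 0, 6)))), 40, 40)
  xs <- matrix(rep(0:39, each = 40), 40, 40); ys <- t(xs)
  tex[(xs - 20)^2 + (ys - 20)^2 <= 5^2] <- 230
  ph <- threshold_phansalkar(calibrated_image(tex, 1),
                             threshold_spec("phansalkar", phansalkar_radius_px = 8))
  lab <- poremorph:::cpp_label(ph$pixels, 8L)
  center_lab <- lab[21, 21]
  expect_gt(center_lab, 0)
  disk_px <- (xs - 20)^2 + (ys - 20)^2 <= 4^2
  expect_true(all(lab[disk_px] == center_lab))
})

test_that("mask union is commutative, idempotent, identity with empty", {
  set.seed(26)
  a <- binary_mask(matrix(runif(100) > 0.5, 10, 10), 1)
  b <- binary_mask(matrix(runif(100) > 0.5, 10, 10), 1)
  e <- binary_mask(matrix(FALSE, 10, 10), 1)
  expect_identical(combine_masks(list(a, e))$pixels, a$pixels)
  expect_identical(combine_masks(list(a, b))$pixels, combine_masks(list(b, a))$pixels)
  expect_identical(combine_masks(list(a, a))$pixels, a$pixels)
  expect_error(combine_masks(list(a, binary_mask(matrix(FALSE, 5, 5), 1))), "shapes")
})

test_that("close_and_fill closes 1-px gaps and fills interiors", {
  e <- binary_mask(matrix(FALSE, 10, 10), 1)
  expect_equal(sum(close_and_fill(e)$pixels), 0)
  # solid disk unchanged
  xs <- matrix(rep(0:29, each = 30), 30, 30); ys <- t(xs)
  disk <- binary_mask((xs - 15)^2 + (ys - 15)^2 <= 8^2, 1)
  expect_identical(close_and_fill(disk)$pixels, disk$pixels)
  # broken ring: 1-px gap, then interior fill
  ring <- (xs - 15)^2 + (ys - 15)^2 <= 8^2 & (xs - 15)^2 + (ys - 15)^2 > 6^2
  ring[15:16, 23:24] <- FALSE
  out <- close_and_fill(binary_mask(ring, 1))
  lab <- poremorph:::cpp_label(out$pixels, 8L)
  expect_equal(max(lab), 1)
  expect_true(out$pixels[16, 16])  # interior filled
})

test_that("distance-map morphology merges, smooths, and respects the identity", {
  xs <- matrix(rep(0:99, each = 100), 100, 100); ys <- t(xs)
  disk <- binary_mask((xs - 50)^2 + (ys - 50)^2 <= 30^2, 1)
  # zero cycles is the identity
  expect_identical(morph_modify(disk, morph_spec(0, 0))$pixels, disk$pixels)
  for (n in c(1, 3, 5)) {
    out <- morph_modify(disk, morph_spec(n, n))
    expect_lt(abs(sum(out$pixels) - sum(disk$pixels)) / sum(disk$pixels), 0.03)
  }
  # two disks 3 px apart merge under 2 closing cycles
  two <- binary_mask((xs - 30)^2 + (ys - 50)^2 <= 10^2 |
                     (xs - 53)^2 + (ys - 50)^2 <= 10^2, 1)
  expect_equal(max(poremorph:::cpp_label(two$pixels, 8L)), 2)
  merged <- morph_modify(two, morph_spec(2, 0))
  expect_equal(max(poremorph:::cpp_label(merged$pixels, 8L)), 1)
  # smoothing removes 1-px boundary spikes, increasing solidity
  spiky <- (xs - 50)^2 + (ys - 50)^2 <= 20^2
  set.seed(27)
  th <- runif(12, 0, 2 * pi)
  for (t in th) {
    sx <- round(50 + 21 * cos(t)); sy <- round(50 + 21 * sin(t))
    spiky[sy + 1, sx + 1] <- TRUE
  }
  sol <- function(m) measure_components(binary_mask(m, 1))$solidity[1]
  sm <- morph_modify(binary_mask(spiky, 1), morph_spec(0, 2))
  expect_gt(sol(sm$pixels), sol(spiky))
})

test_that("filter_candidates applies strict size/circularity cuts and conserves", {
  # 1999 um^2 square (at 1 um/px) is removed by a 2000 um^2 filter;
  # a disk of equal area passes the circularity cut
  m <- matrix(FALSE, 120, 260)
  m[10:30, 10:105] <- TRUE                # 21 x 96 = 2016 px, elongated
  m[60:98, 10:60] <- TRUE                 # 39 x 51 = 1989 px
  xs <- matrix(rep(0:259, each = 120), 120, 260); ys <- t(matrix(rep(0:119, each = 260), 260, 120))
  m[(xs - 180)^2 + (ys - 60)^2 <= 26^2] <- TRUE
  pores <- filter_candidates(binary_mask(m, 1), morph_spec(min_size_um2 = 2000,
                                                           min_circularity = 0))
  expect_equal(nrow(pores), 2)            # 1989 px^2 component dropped
  pores2 <- filter_candidates(binary_mask(m, 1),
                              morph_spec(min_size_um2 = 2000, min_circularity = 0.9))
  expect_equal(nrow(pores2), 1)           # only the disk is circular enough
  expect_gt(pores2$circularity[1], 0.9)
  # conservation: zero filters return every component
  set.seed(28)
  blob <- matrix(runif(2500) > 0.7, 50, 50)
  all_comp <- filter_candidates(binary_mask(blob, 1),
                                morph_spec(min_size_um2 = 0, min_circularity = 0))
  expect_equal(nrow(all_comp), max(poremorph:::cpp_label(blob, 8L)))
  # survivor count matches an independent labeling + filtering oracle
  lab <- poremorph:::cpp_label(blob, 8L)
  sizes <- tabulate(lab[lab > 0])
  got <- filter_candidates(binary_mask(blob, 1),
                           morph_spec(min_size_um2 = 3, min_circularity = 0))
  expect_equal(nrow(got), sum(sizes > 3))
})

test_that("extract_pores keeps every candidate inside the cortex", {
  bp <- small_section(noise_sd = 6)
  gen <- generate_section(bp)
  cleared <- auto_clear(gen$image, min_hole_px = 2000)
  borders <- derive_borders(cleared)
  pores <- extract_pores(cleared, borders,
                         threshold_spec(), morph_spec(min_size_um2 = 500))
  expect_equal(nrow(pores), 3)
  outside <- !borders$cortical_mask$pixels
  for (idx in pores$pixels) expect_false(any(outside[idx]))
})
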