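# Regional subdivision and gray-mean pore assignment.

annulus_borders <- function(dim = 300, outer = 120, inner = 50, shift = c(0, 0)) {
  px <- matrix(0, dim, dim)
  xs <- matrix(rep(0:(dim - 1), each = dim), dim, dim); ys <- t(xs)
  c0 <- (dim - 1) / 2
  ann <- (xs - c0 - shift[1])^2 + (ys - c0 - shift[2])^2 <= outer^2 &
         (xs - c0 - shift[1])^2 + (ys - c0 - shift[2])^2 > inner^2
  px[ann] <- 150
  derive_borders(calibrated_image(px, 1))
}

test_that("principal axis matches the moment-tensor eigen decomposition", {
  rect <- matrix(FALSE, 200, 300)
  rect[51:150, 51:250] <- TRUE  # 200 wide x 100 tall
  ax <- principal_axis(rect)
  expect_equal(ax$angle_deg, 0)
  expect_equal(unname(ax$centroid), c(149.5, 99.5))
  ax90 <- principal_axis(t(rect))
  expect_equal(ax90$angle_deg, 90)
  set.seed(43)
  for (i in 1:5) {
    m <- random_blob_mask(40, 40)
    ax <- principal_axis(m)
    idx <- which(m); h <- nrow(m)
    pysx <- cbind((idx - 1) %/% h, (idx - 1) %% h)  # (x, y)
    cov <- stats::cov.wt(pysx, method = "ML")$cov
    ev <- eigen(cov)$vectors[, 1]
    ang <- (atan2(ev[2], ev[1]) * 180 / pi) %% 180
    expect_equal(ax$angle_deg, ang, tolerance = 1e-6)
  }
  expect_error(principal_axis(matrix(FALSE, 5, 5)), "empty")
})

test_that("quadrant split partitions the cortex exactly into equal quarters", {
  borders <- annulus_borders()
  part <- split_quadrants(borders)
  masks <- part$region_masks
  # pairwise disjoint and exhaustive
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_true(all(total[borders$cortical_mask$pixels] == 1))
  expect_true(all(total[!borders$cortical_mask$pixels] == 0))
  areas <- vapply(masks, sum, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.005)
  expect_error(split_quadrants(borders, names = c("A", "A", "B", "C")), "distinct")
})

test_that("rotating the image by 90 degrees permutes quadrant masks cyclically", {
  borders <- annulus_borders(shift = c(20, 10))
  part <- split_quadrants(borders, "image_aligned", c("N1", "N2", "N3", "N4"))
  # rotate the cleared image 90 degrees counter-clockwise on screen
  rot_mat <- function(m) t(m)[ncol(m):1, ]
  px_rot <- rot_mat(borders$cortical_mask$pixels)
  b2 <- derive_borders(calibrated_image(px_rot * 150, 1))
  p2 <- split_quadrants(b2, "image_aligned", c("N1", "N2", "N3", "N4"))
  a1 <- vapply(part$region_masks, sum, numeric(1))
  a2 <- vapply(p2$region_masks, sum, numeric(1))
  expect_equal(unname(a2), unname(a1[c(2, 3, 4, 1)]), tolerance = 0.002)
})

test_that("rib split halves a symmetric annulus and flags the rounder half pleural", {
  borders <- annulus_borders()
  expect_warning(sp <- split_rib(borders), "isotropic")
  areas <- vapply(sp$partition$region_masks, sum, numeric(1))
  expect_lt(abs(diff(areas)) / mean(areas), 0.01)
  total <- Reduce(`|`, sp$partition$region_masks)
  expect_identical(total, borders$cortical_mask$pixels)
  # crescent rib: thin sliver half vs rounder thick half
  bp <- section_blueprint("crescent_rib", dim_px = c(320, 460),
                          outer = c(210, 120), inner = c(170, 80),
                          inner_offset = c(0, 25),
                          pores = data.frame(x = numeric(0), y = numeric(0),
                                             r_px = numeric(0)))
  gen <- generate_section(bp)
  cleared <- auto_clear(gen$image, min_hole_px = 2000)
  b <- derive_borders(cleared)
  sp2 <- split_rib(b)
  circs <- sp2$half_circularities
  expect_false(isTRUE(all.equal(circs[1], circs[2])))
  # the guess goes to the half with the higher silhouette circularity
  got <- names(sp2$partition$region_masks)[if (circs[1] >= circs[2]) 1 else 2]
  expect_equal(got, "Pleural")
})

test_that("gray-mean assignment equals the overlap-count argmax and scores 255/0", {
  borders <- annulus_borders()
  part <- split_quadrants(borders)
  cm <- borders$cortical_mask$pixels
  # a pore fully inside one region scores 255 there, 0 elsewhere
  anterior <- part$region_masks[[1]]
  idx_in <- which(anterior & poremorph:::binary_erode(anterior, 4))[1:50]
  pores <- tibble::tibble(pixels = list(idx_in))
  got <- assign_pores(pores, part)
  expect_equal(got$region[1], part$region_names[1])
  expect_equal(unname(got$gray_means[1, ]), c(255, 0, 0, 0))
  # straddling pore: 60/40 split -> means 153 vs 102
  b1 <- which(anterior)[1:60]
  b2 <- which(part$region_masks[[2]])[1:40]
  p2 <- tibble::tibble(pixels = list(c(b1, b2)))
  g2 <- assign_pores(p2, part)
  expect_equal(unname(sort(g2$gray_means[1, ], decreasing = TRUE)[1:2]), c(153, 102))
  expect_equal(g2$region[1], part$region_names[1])
  # exact 50/50 tie goes to the first region in name order, with a notice
  p3 <- tibble::tibble(pixels = list(c(b1[1:40], b2)))
  expect_message(g3 <- assign_pores(p3, part), "tie")
  expect_equal(g3$region[1], part$region_names[1])
  # outside-cortex pore is flagged unassigned with a warning
  p4 <- tibble::tibble(pixels = list(which(!cm)[1:10]))
  expect_warning(g4 <- assign_pores(p4, part), "unassigned")
  expect_equal(g4$region[1], "unassigned")
})

test_that("gray-mean argmax agrees with pixel-count argmax on random fixtures", {
  set.seed(44)
  borders <- annulus_borders(200, 80, 30)
  cm <- borders$cortical_mask$pixels
  cort_idx <- which(cm)
  for (trial in 1:60) {
    theta <- runif(1, 0, pi)
    part <- split_quadrants(borders,
                            sample(c("image_aligned", "major_axis"), 1),
                            c("R1", "R2", "R3", "R4"))
    pore <- sample(cort_idx, sample(20:200, 1))
    pores <- tibble::tibble(pixels = list(pore))
    got <- suppressWarnings(assign_pores(pores, part))
    counts <- vapply(part$region_masks, function(m) sum(m[pore]), numeric(1))
    expect_equal(got$region[1], part$region_names[which.max(counts)])
  }
})

test_that("assignment is invariant to region rendering order", {
  borders <- annulus_borders(200, 80, 30)
  part <- split_quadrants(borders, names = c("A", "B", "C", "D"))
  rev_part <- poremorph::region_partition(rev(part$region_masks), part$axis_used,
                                          part$centroid, 1)
  set.seed(45)
  pore <- sample(which(borders$cortical_mask$pixels), 120)
  p <- tibble::tibble(pixels = list(pore))
  r1 <- assign_pores(p, part)$region[1]
  r2 <- assign_pores(p, rev_part)$region[1]
  expect_equal(r1, r2)
})
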