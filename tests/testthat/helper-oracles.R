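# Independent oracles and shared fixtures. Every oracle here is implemented
# from the mathematical definition, independently of the package kernels.

# breadth-first tolerance flood fill (wand oracle)
oracle_flood <- function(g, seed_xy, tol, conn = 8) {
  h <- nrow(g); w <- ncol(g)
  sx <- seed_xy[1] + 1; sy <- seed_xy[2] + 1
  v <- g[sy, sx]
  out <- matrix(FALSE, h, w)
  queue <- list(c(sy, sx))
  out[sy, sx] <- TRUE
  nb <- if (conn == 8) expand.grid(dy = -1:1, dx = -1:1) else
    data.frame(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  nb <- nb[!(nb$dy == 0 & nb$dx == 0), ]
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(nb))) {
      y <- p[1] + nb$dy[k]; x <- p[2] + nb$dx[k]
      if (y < 1 || y > h || x < 1 || x > w || out[y, x]) next
      if (abs(g[y, x] - v) <= tol) { out[y, x] <- TRUE; queue <- c(queue, list(c(y, x))) }
    }
  }
  out
}

# brute-force even-odd point-in-polygon over all pixel centers
oracle_rasterize <- function(xs, ys, h, w) {
  out <- matrix(FALSE, h, w)
  n <- length(xs)
  for (py in 0:(h - 1)) for (px in 0:(w - 1)) {
    crossings <- 0
    on_edge <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[j]; y2 <- ys[j]
      # on-boundary check
      len2 <- (x2 - x1)^2 + (y2 - y1)^2
      t <- if (len2 > 0) ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / len2 else 0
      t <- min(1, max(0, t))
      if ((px - (x1 + t * (x2 - x1)))^2 + (py - (y1 + t * (y2 - y1)))^2 < 1e-12)
        on_edge <- TRUE
      if ((y1 <= py) != (y2 <= py)) {
        xc <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (xc < px - 1e-9) crossings <- crossings + 1
      }
    }
    out[py + 1, px + 1] <- on_edge || (crossings %% 2 == 1)
  }
  out
}

# vectorized brute-force nearest-foreground-pixel distance
oracle_edt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  fy <- (idx - 1) %% h; fx <- (idx - 1) %/% h
  out <- matrix(NA_real_, h, w)
  for (x in 0:(w - 1)) {
    dx2 <- (fx - x)^2
    for (y in 0:(h - 1)) out[y + 1, x + 1] <- sqrt(min(dx2 + (fy - y)^2))
  }
  out
}

# direct per-pixel Phansalkar evaluation (clipped disk neighborhood)
oracle_phansalkar <- function(g, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  gn <- g / 255
  h <- nrow(g); w <- ncol(g)
  out <- matrix(FALSE, h, w)
  for (py in seq_len(h)) for (px in seq_len(w)) {
    vals <- c()
    for (dy in -radius:radius) for (dx in -radius:radius) {
      if (dy^2 + dx^2 > radius^2) next
      yy <- py + dy; xx <- px + dx
      if (yy < 1 || yy > h || xx < 1 || xx > w) next
      vals <- c(vals, gn[yy, xx])
    }
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    thr <- m * (1 + p * exp(-q * m) + k * ((s / r) - 1))
    out[py, px] <- gn[py, px] > thr
  }
  out
}

random_polygon <- function(n_vertices = sample(3:12, 1), scale = 50) {
  # star-shaped random polygon; coordinates quantized to 1/4 px so they are
  # exactly representable in the archive's 32-bit floats
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 5, scale)
  x <- round(4 * (scale + rad * cos(ang))) / 4
  y <- round(4 * (scale + rad * sin(ang))) / 4
  roi_polygon(x, y, name = paste0("poly-", paste(sample(letters, 5), collapse = "")))
}

random_blob_mask <- function(h = 40, w = 40, n_seeds = 3, grow = 60) {
  m <- matrix(FALSE, h, w)
  ys <- sample(seq(8, h - 8), n_seeds, replace = TRUE)
  xs <- sample(seq(8, w - 8), n_seeds, replace = TRUE)
  for (k in seq_len(n_seeds)) m[ys[k], xs[k]] <- TRUE
  for (i in seq_len(grow)) {
    edge <- which(m)
    pick <- edge[sample(length(edge), 1)]
    py <- (pick - 1) %% h + 1; px <- (pick - 1) %/% h + 1
    dy <- sample(-1:1, 1); dx <- sample(-1:1, 1)
    yy <- min(max(py + dy, 2), h - 1); xx <- min(max(px + dx, 2), w - 1)
    m[yy, xx] <- TRUE
  }
  m
}

# shared, memoized default-world pipeline runs (used by several test files)
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline_run <- function(noise = FALSE) {
  key <- if (noise) "noisy" else "clean"
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  bp <- section_blueprint(rng_seed = 7,
                          noise_sd = if (noise) 8 else 0,
                          illumination_gradient = if (noise) 10 else 0)
  gen <- generate_section(bp)
  cleared <- auto_clear(gen$image)
  borders <- derive_borders(cleared)
  pores <- extract_pores(cleared, borders)
  analysis <- analyze_section(cleared, pores, "long_bone", borders = borders)
  res <- list(bp = bp, gen = gen, cleared = cleared, borders = borders,
              pores = pores, analysis = analysis)
  .pipeline_cache[[key]] <- res
  res
}

# small fast annulus for module-level tests
small_section <- function(rng_seed = 3, pores = NULL, noise_sd = 0) {
  if (is.null(pores))
    pores <- data.frame(x = c(200 + 110, 200 - 110, 200),
                        y = c(200, 200, 200 + 150),
                        r_px = c(18, 22, 20))
  section_blueprint("annulus", dim_px = c(400, 400), outer = 180, inner = 80,
                    pores = pores, noise_sd = noise_sd, rng_seed = rng_seed)
}

match_truth <- function(pores, truth) {
  vapply(seq_len(nrow(pores)), function(i) {
    d <- sqrt((truth$x - pores$centroid_x[i])^2 + (truth$y - pores$centroid_y[i])^2)
    which.min(d)
  }, integer(1))
}
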