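# Whole-section analysis: regional subdivision, pore typing, and the three
# summary tables (cross-sectional geometry; total-section morphometry by
# pore type; regional morphometry by pore type) plus the per-pore listing.

pore_set_from_polygons <- function(polygons, shape, scale_um_per_px,
                                   perimeter_convention = "kulpa") {
  rows <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    mask <- rasterize_roi(p, shape, scale_um_per_px)
    idx <- which(mask$pixels)
    if (!length(idx)) stop("pore polygon ", i, " rasterizes to no pixels")
    h <- shape[1]
    lab <- cpp_label(mask$pixels, 8L)
    perim_px <- if (perimeter_convention == "kulpa") chain_perimeter_px(lab, 1L)
                else polygon_perimeter(p$x, p$y)
    m <- pore_metrics_row(p, (idx - 1) %/% h, (idx - 1) %% h,
                          scale_um_per_px, perim_px)
    m$id <- i
    m$name <- if (nzchar(p$name)) p$name else sprintf("%04d", i)
    m$centroid_x <- mean((idx - 1) %/% h)
    m$centroid_y <- mean((idx - 1) %% h)
    m$polygon <- list(p)
    m$pixels <- list(idx)
    m
  })
  out <- do.call(rbind, rows)
  out <- out[, pore_set_columns()]
  attr(out, "scale_um_per_px") <- scale_um_per_px
  attr(out, "image_dim") <- shape
  class(out) <- c("pore_set", class(out))
  out
}

#' Full morphometric analysis of a cleared section
#'
#' Runs the whole reporting stage: border-derived geometry, regional
#' subdivision (rib halves or long-bone quadrants), endosteal distance-map
#' pore typing, and the three summary tables plus the per-pore listing.
#'
#' @param cleared a cleared `calibrated_image`.
#' @param pores a `pore_set` tibble (from [extract_pores()]) or a list of
#'   closed [roi_polygon()] (e.g. a manually produced archive).
#' @param section_type `"long_bone"` (quadrants) or `"rib"` (halves).
#' @param region_names labels: 4 for quadrants, ignored for ribs.
#' @param alignment quadrant starting-axis choice, see [split_quadrants()].
#' @param axis_choice rib axis, see [split_rib()].
#' @param borders optional precomputed [border_set()].
#' @param perimeter_convention see [measure_components()].
#' @return list with `geometry` (one-row tibble), `totals` and `regional`
#'   (summary tibbles by pore type), `pores` (typed, labeled per-pore
#'   tibble), `borders`, `partition`, and for ribs `pleural_guess`.
#' @export
analyze_section <- function(cleared, pores,
                            section_type = c("long_bone", "rib"),
                            region_names = c("Anterior", "Lateral", "Posterior", "Medial"),
                            alignment = "image_aligned",
                            axis_choice = "major",
                            borders = NULL,
                            perimeter_convention = "kulpa") {
  section_type <- match.arg(section_type)
  if (is.null(borders)) borders <- derive_borders(cleared)
  scale <- borders$scale_um_per_px
  if (!inherits(pores, "pore_set")) {
    pores <- pore_set_from_polygons(pores, dim(borders$cortical_mask$pixels),
                                    scale, perimeter_convention)
  }
  pleural_guess <- NULL
  if (section_type == "rib") {
    sp <- split_rib(borders, axis_choice)
    partition <- sp$partition
    pleural_guess <- sp$pleural_guess
  } else {
    partition <- split_quadrants(borders, alignment, region_names)
  }
  pores <- assign_pores(pores, partition)
  pores <- classify_pores(pores, borders)
  geometry <- section_geometry(borders, pores)

  ct_area_um2 <- sum(borders$cortical_mask$pixels) * scale^2
  tt_area_um2 <- border_areas_px(borders)[["tt"]] * scale^2
  types <- c("Total", "cortical", "trabecularized")
  sel_type <- function(t) if (t == "Total") rep(TRUE, nrow(pores)) else pores$type == t
  totals <- do.call(rbind, lapply(types, function(t)
    summarize_pores(pores[sel_type(t), ], ct_area_um2, tt_area_um2,
                    region = "All", type = t)))
  region_names_used <- partition$region_names
  if (any(pores$region == "unassigned"))
    region_names_used <- c(region_names_used, "unassigned")
  regional <- do.call(rbind, lapply(region_names_used, function(r) {
    ra <- if (r == "unassigned") ct_area_um2
          else sum(partition$region_masks[[r]]) * scale^2
    do.call(rbind, lapply(types, function(t)
      summarize_pores(pores[pores$region == r & sel_type(t), ], ra, tt_area_um2,
                      region = r, type = t)))
  }))
  list(geometry = geometry, totals = totals, regional = regional,
       pores = pores, borders = borders, partition = partition,
       pleural_guess = pleural_guess)
}

per_pore_table <- function(pores) {
  keep <- setdiff(names(pores), c("polygon", "pixels", "gray_means"))
  out <- as.data.frame(pores[, keep])
  if ("gray_means" %in% names(pores)) {
    gm <- pores$gray_means
    colnames(gm) <- paste0("gray_mean_", colnames(gm))
    out <- cbind(out, as.data.frame(gm))
  }
  tibble::as_tibble(out)
}

#' Write the analysis spreadsheets
#'
#' Writes the cross-sectional geometry, total-section morphometry by pore
#' type, regional morphometry by pore type, per-pore listing (regional
#' assignment, pore type, morphometry) and the regional gray-means table as
#' CSV files ("." decimal, UTF-8, header row).
#'
#' @param analysis result of [analyze_section()].
#' @param output_dir directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_analysis_csvs <- function(analysis, output_dir, prefix = "section") {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    geometry = file.path(output_dir, paste0(prefix, "_cross_sectional_geometry.csv")),
    totals = file.path(output_dir, paste0(prefix, "_total_morphometry_by_type.csv")),
    regional = file.path(output_dir, paste0(prefix, "_regional_morphometry_by_type.csv")),
    pores = file.path(output_dir, paste0(prefix, "_pores.csv")),
    gray = file.path(output_dir, paste0(prefix, "_regional_gray_means.csv")))
  write.csv(analysis$geometry, paths["geometry"], row.names = FALSE)
  write.csv(analysis$totals, paths["totals"], row.names = FALSE)
  write.csv(analysis$regional, paths["regional"], row.names = FALSE)
  pp <- per_pore_table(analysis$pores)
  write.csv(pp, paths["pores"], row.names = FALSE)
  gm_cols <- grep("^gray_mean_", names(pp), value = TRUE)
  write.csv(pp[, c("id", "name", "region", gm_cols)], paths["gray"], row.names = FALSE)
  invisible(paths)
}
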