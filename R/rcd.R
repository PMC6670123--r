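#' Pipeline configuration
#'
#' Collects the geometric and algorithmic constants of the quantification
#' pipeline. Defaults follow the published acquisition and analysis
#' geometry: a 3 mm field upsampled to a 1024-px working grid, a 2.5 mm
#' diameter macular analysis zone, and a fixed 0.6 mm diameter foveal
#' exclusion / noise-baseline disc.
#'
#' @param extent_mm physical field side length, mm.
#' @param target_px working resolution after bicubic upsampling.
#' @param zone_outer_diameter_mm outer diameter of the analysis zone, mm.
#' @param faz_exclusion_diameter_mm diameter of the excluded foveal disc
#'   (also the noise-baseline disc), mm.
#' @param zone_anchor `"faz"` (default) anchors the analysis zone on the
#'   detected FAZ centroid; `"image"` uses the field center. Scans are
#'   fovea-centered, so the two normally differ by a fraction of a
#'   millimeter; the FAZ centroid is the better estimate of the foveal
#'   center when detection succeeds.
#' @param srcl_map,drcl_map which binary map feeds the density for each
#'   layer: the superficial layer uses the capillary-only (`"small"`) map —
#'   large vessels are removed — while the deep layer, which carries no
#'   arteriole/venule trunks, uses the despeckled all-vessel (`"all"`) map.
#' @param level_set a [level_set_params()].
#' @param threshold a [threshold_spec()]. `min_width_px` is interpreted at
#'   the 1024-px / 3-mm reference grid and rescaled to the actual working
#'   calibration.
#' @return A list of class `rcd_config`.
#' @export
rcd_config <- function(extent_mm = 3.0, target_px = 1024L,
                       zone_outer_diameter_mm = 2.5,
                       faz_exclusion_diameter_mm = 0.6,
                       zone_anchor = c("faz", "image"),
                       srcl_map = "small", drcl_map = "all",
                       level_set = level_set_params(),
                       threshold = threshold_spec()) {
  zone_anchor <- match.arg(zone_anchor)
  stopifnot(srcl_map %in% c("small", "all"), drcl_map %in% c("small", "all"))
  structure(list(extent_mm = extent_mm, target_px = as.integer(target_px),
                 zone_outer_diameter_mm = zone_outer_diameter_mm,
                 faz_exclusion_diameter_mm = faz_exclusion_diameter_mm,
                 zone_anchor = zone_anchor, srcl_map = srcl_map,
                 drcl_map = drcl_map, level_set = level_set,
                 threshold = threshold),
            class = "rcd_config")
}

config_digest <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  paste0(names(flat), "=", vapply(flat, format, character(1), digits = 10),
         collapse = ";")
}

#' Capillary density over an analysis zone
#'
#' RCD (%) is the proportion of the analysis zone occupied by perfused
#' (set) pixels: `100 * n_vessel_px / n_zone_px`.
#'
#' @param vessel_map logical matrix of perfused pixels.
#' @param zone a `region_mask` congruent with the map (normally the
#'   2.5 mm annulus excluding the foveal disc).
#' @param layer layer tag recorded in the result.
#' @return A list of class `rcd_result`: `layer`, `rcd_percent`,
#'   `n_vessel_px`, `n_zone_px`, `zone_center`.
#' @export
compute_rcd <- function(vessel_map, zone, layer = "unknown") {
  stopifnot(is.logical(vessel_map), inherits(zone, "region_mask"))
  if (!identical(dim(vessel_map), dim(zone$mask)))
    stop("vessel map and zone mask have different shapes")
  n_zone <- sum(zone$mask)
  if (n_zone == 0) stop("analysis zone is empty")
  n_vessel <- sum(vessel_map & zone$mask)
  structure(
    list(layer = layer, rcd_percent = 100 * n_vessel / n_zone,
         n_vessel_px = n_vessel, n_zone_px = n_zone,
         zone_center = zone$center_px, faz_area_mm2 = NA_real_,
         config_digest = ""),
    class = "rcd_result")
}

#' @export
print.rcd_result <- function(x, ...) {
  cat(sprintf("rcd_result [%s]: RCD = %.1f%% (%d / %d px in zone)\n",
              x$layer, x$rcd_percent, x$n_vessel_px, x$n_zone_px))
  if (!is.na(x$faz_area_mm2))
    cat(sprintf("  FAZ area %.4f mm2, zone center (%.1f, %.1f) px\n",
                x$faz_area_mm2, x$zone_center[1], x$zone_center[2]))
  invisible(x)
}

#' Quantify capillary density of one en-face image, end to end
#'
#' Runs the full pipeline: bicubic upsampling to the working grid, FAZ
#' detection (or a user-supplied override mask), the fixed-diameter noise
#' baseline disc, global + adaptive binarization with large-vessel
#' subtraction, and the density over the annular analysis zone. For the
#' superficial layer the density is computed on the capillary-only map
#' (large vessels removed); for the deep layer on the despeckled all-vessel
#' map (see [rcd_config()]).
#'
#' @param img an [enface_image()].
#' @param layer `"SRCL"` or `"DRCL"`; defaults to the image's tag.
#' @param config an [rcd_config()].
#' @param faz_mask optional logical matrix (at working resolution) that
#'   overrides FAZ detection — the hook for manually corrected
#'   segmentations. Its centroid anchors the baseline disc.
#' @return An `rcd_result` with `faz_area_mm2` and `config_digest` filled
#'   in, plus attributes `maps` (the `vessel_maps`) and `faz`.
#' @export
quantify_image <- function(img, layer = img$layer, config = rcd_config(),
                           faz_mask = NULL) {
  stopifnot(inherits(img, "enface_image"))
  if (!layer %in% c("SRCL", "DRCL"))
    stop("layer must be 'SRCL' or 'DRCL'")
  work <- upsample_bicubic(img, config$target_px)
  if (is.null(faz_mask)) {
    faz <- detect_faz(work, config$level_set)
  } else {
    if (!identical(dim(faz_mask), dim(work$pixels)))
      stop("faz_mask must match the working resolution (",
           config$target_px, " px)")
    idx <- which(faz_mask, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("faz_mask override is empty")
    faz <- structure(
      list(contour = faz_contour(faz_mask),
           centroid_px = c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5),
           area_mm2 = nrow(idx) / work$px_per_mm^2, mask = faz_mask,
           converged = TRUE, iterations_used = 0L),
      class = "faz_boundary")
  }
  baseline <- noise_baseline_disc(faz, work,
                                  config$faz_exclusion_diameter_mm)
  # pixel-unit thresholds are defined at the 1024-px / 3-mm reference
  # calibration and rescaled to the working grid (areas by the square)
  spec <- config$threshold
  ratio <- work$px_per_mm / (1024 / 3)
  spec$min_width_px <- spec$min_width_px * ratio
  w <- max(3L, as.integer(round(spec$adaptive_window_px * ratio)))
  spec$adaptive_window_px <- w + (1L - w %% 2L)
  spec$min_object_px <- as.integer(round(spec$min_object_px * ratio^2))
  maps <- binarize_vessels(work, baseline, spec)
  center <- if (config$zone_anchor == "faz") faz$centroid_px
            else image_center_px(work)
  zone <- make_annulus_mask(
    work, center,
    inner_radius_mm = config$faz_exclusion_diameter_mm / 2,
    outer_radius_mm = config$zone_outer_diameter_mm / 2)
  map <- switch(if (layer == "SRCL") config$srcl_map else config$drcl_map,
                small = maps$small_map, all = maps$all_map)
  res <- compute_rcd(map, zone, layer = layer)
  res$faz_area_mm2 <- faz$area_mm2
  res$config_digest <- config_digest(config)
  attr(res, "maps") <- maps
  attr(res, "faz") <- faz
  res
}
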