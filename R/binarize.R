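#' Threshold parameters for vessel binarization
#'
#' Two binarizations are produced from each en-face image: a global
#' threshold derived from the noise statistics of the foveal baseline disc,
#' which (after a width criterion) retains only the large vessels, and a
#' local-mean adaptive threshold that retains large and small vessels.
#'
#' @param k_noise multiplier for the global threshold, which is
#'   `mean(baseline) + k_noise * sd(baseline)`. The default 6 was
#'   calibrated on phantoms so the global image truly "contains only the
#'   large vessels": it places the cut well above the capillary signal
#'   (which sits a few noise SDs over the baseline) but far below
#'   arteriole/venule decorrelation.
#' @param adaptive_window_px side of the local-mean window for the adaptive
#'   threshold; odd, `>= 3` (default 101 px at the 1024-px / 3-mm
#'   reference grid, about 0.3 mm — several capillary spacings, so the
#'   mesh does not mask itself; rescaled to the working calibration by
#'   [quantify_image()]).
#' @param adaptive_offset constant added to the local mean before comparison
#'   (default 0; intensities must strictly exceed local mean + offset).
#' @param min_object_px connected components smaller than this are removed
#'   from the adaptive map as background speckle (default 20 px at the
#'   1024-px / 3-mm reference grid; rescaled by area in
#'   [quantify_image()]).
#' @param floor_k_noise noise-floor multiplier for the adaptive map: a
#'   pixel must exceed both the local mean (+ offset) and
#'   `baseline mean + floor_k_noise * baseline SD`. The floor is the
#'   conventional few-SDs-above-noise flow cut (default 2.5, i.e. a
#'   ~0.6% false-positive rate on Gaussian background); without it a
#'   mean-relative threshold marks about half of any signal-free region.
#' @param min_width_px large-vessel width criterion: the global map is
#'   opened with a disc of this diameter and components whose median
#'   centerline width falls below it are discarded, so bright capillaries
#'   do not survive the global cut (default 8 px at 1024-px / 3-mm, about
#'   23 um — comfortably above capillary caliber, far below
#'   arteriole/venule caliber; scaled by calibration in
#'   [quantify_image()]).
#' @return A list of class `threshold_spec`.
#' @export
threshold_spec <- function(k_noise = 6, adaptive_window_px = 101L,
                           adaptive_offset = 0, min_object_px = 20L,
                           floor_k_noise = 2.5, min_width_px = 8) {
  adaptive_window_px <- as.integer(adaptive_window_px)
  if (adaptive_window_px < 3L || adaptive_window_px %% 2L == 0L)
    stop("adaptive_window_px must be odd and >= 3")
  if (min_object_px < 0) stop("min_object_px must be >= 0")
  structure(list(k_noise = k_noise,
                 adaptive_window_px = adaptive_window_px,
                 adaptive_offset = adaptive_offset,
                 min_object_px = as.integer(min_object_px),
                 floor_k_noise = floor_k_noise,
                 min_width_px = min_width_px),
            class = "threshold_spec")
}

#' Remove small connected components from a binary map
#'
#' @param map logical matrix.
#' @param min_px components (8-connected) with fewer pixels are dropped.
#' @return The despeckled logical matrix.
#' @export
despeckle <- function(map, min_px) {
  if (min_px <= 1) return(map)
  lab <- label_components_cpp(map, 8L)
  if (max(lab) == 0) return(map)
  keep <- tabulate(lab) >= min_px
  map & keep[pmax(lab, 1L)] & (lab > 0)
}

#' Global (noise-baseline) threshold: large-vessel map
#'
#' The threshold is `mean + k_noise * sd` of the intensities inside the
#' baseline disc, which samples the avascular (signal-free) foveal center.
#' Pixels strictly above threshold are flow signal; because bright
#' capillaries can also exceed a purely global cut, connected components
#' whose median centerline width (twice the chamfer distance-transform
#' value on the ridge, minus one) is below `min_width_px` are removed, so
#' only vessels of arteriole/venule caliber remain.
#'
#' @param img an [enface_image()].
#' @param baseline a `region_mask` (the [noise_baseline_disc()]).
#' @param spec a [threshold_spec()].
#' @return A list: `map` (logical large-vessel matrix), `threshold`
#'   (the global threshold value).
#' @export
global_threshold_large <- function(img, baseline, spec = threshold_spec()) {
  stopifnot(inherits(img, "enface_image"), inherits(baseline, "region_mask"))
  vals <- img$pixels[baseline$mask]
  if (length(vals) == 0) stop("baseline mask is empty")
  s <- stats::sd(vals)
  if (length(vals) < 2 || s == 0) {
    if (spec$k_noise > 0)
      warning("baseline SD is zero; global threshold equals the baseline mean")
    s <- 0
  }
  thr <- mean(vals) + spec$k_noise * s
  raw <- img$pixels > thr
  list(map = filter_by_width(raw, spec$min_width_px), threshold = thr)
}

# morphological opening with a Euclidean disc of radius r (px), via the
# chamfer distance transform: erosion keeps pixels deeper than r, dilation
# restores a band of width r around what survives
# r_dilate < r gives a conservative reclaim: the global map fattens true
# trunks by their blur halo, so restoring slightly less than was eroded
# recovers the true caliber instead of the halo caliber
open_disc <- function(map, r, r_dilate = r) {
  if (r <= 0 || !any(map)) return(map)
  eroded <- chamfer_dt_cpp(map) > r
  if (!any(eroded)) return(eroded)
  eroded | (chamfer_dt_cpp(!eroded) <= r_dilate)
}

# Large-vessel purification. A single intensity cut keeps bright
# capillaries too, and the capillary mesh touches the large vessels, so a
# purely per-component criterion sees one merged component. An opening
# with a disc of diameter min_width_px first erases everything thinner
# than the width criterion (disconnecting the mesh from the trunks); the
# per-component median centerline width test then drops the residual
# junction blobs that survive the opening.
filter_by_width <- function(map, min_width_px) {
  if (!any(map)) return(map)
  map <- open_disc(map, min_width_px / 2, max(min_width_px / 2 - 0.5, 0))
  if (!any(map)) return(map)
  lab <- label_components_cpp(map, 8L)
  dt <- chamfer_dt_cpp(map)
  ridge <- ridge_cpp(dt, map)
  n_lab <- max(lab)
  widths <- rep(0, n_lab)
  rl <- lab[ridge]
  rd <- dt[ridge]
  for (l in seq_len(n_lab)) {
    w <- rd[rl == l]
    if (length(w)) widths[l] <- 2 * stats::median(w) - 1
  }
  # junction blobs can match the width cut at small sizes; a true trunk
  # is also long, so require a minimal component area as well
  sizes <- tabulate(lab, n_lab)
  keep <- widths >= min_width_px & sizes >= (2 * min_width_px)^2
  map & (lab > 0) & keep[pmax(lab, 1L)]
}

#' Adaptive (local-mean) threshold: all-vessel map
#'
#' A pixel is vessel iff its intensity strictly exceeds the mean of its
#' `adaptive_window_px` neighborhood plus `adaptive_offset`; components
#' smaller than `min_object_px` are then removed as background speckle.
#' When an exclusion mask is supplied (the large-vessel map in the full
#' pipeline), excluded pixels do not enter the local mean: a bright
#' arteriole trunk would otherwise raise the local background estimate and
#' mask the capillaries beside it.
#'
#' @inheritParams global_threshold_large
#' @param exclude optional logical matrix of pixels to leave out of the
#'   local mean (they are still thresholded themselves).
#' @param floor absolute intensity floor a vessel pixel must also exceed
#'   (the noise floor of the baseline disc in the full pipeline; default
#'   `-Inf`, i.e. purely mean-relative).
#' @return A logical matrix of all (large + small) vessel pixels.
#' @export
adaptive_threshold_all <- function(img, spec = threshold_spec(),
                                   exclude = NULL, floor = -Inf) {
  stopifnot(inherits(img, "enface_image"))
  if (spec$adaptive_window_px > min(img$height_px, img$width_px))
    stop("adaptive window (", spec$adaptive_window_px,
         " px) is larger than the image")
  local_mean <- if (is.null(exclude))
    box_mean_cpp(img$pixels, spec$adaptive_window_px)
  else
    masked_box_mean_cpp(img$pixels, spec$adaptive_window_px, exclude)
  map <- img$pixels > pmax(local_mean + spec$adaptive_offset, floor)
  despeckle(map, spec$min_object_px)
}

#' Subtract the large-vessel map from the all-vessel map
#'
#' `small = all AND NOT large`, pixelwise — the capillary-only map.
#'
#' @param all_map,large_map congruent logical matrices.
#' @return Logical matrix of small-vessel (capillary) pixels.
#' @export
subtract_maps <- function(all_map, large_map) {
  if (!identical(dim(all_map), dim(large_map)))
    stop("all_map and large_map have different shapes")
  all_map & !large_map
}

#' Build the three binary perfusion maps of an en-face image
#'
#' Runs the global (large-vessel) and adaptive (all-vessel) binarizations
#' and their subtraction. The large map is harmonized — intersected with
#' the all map — before subtraction, so the set identity
#' `small == all & !large` and pixel conservation
#' `|small| + |all & large| == |all|` hold exactly even where the two
#' thresholds disagree at isolated pixels.
#'
#' @inheritParams global_threshold_large
#' @return A list of class `vessel_maps`: `all_map`, `large_map`,
#'   `small_map` (logical matrices), `threshold_global`, `provenance`
#'   (the `threshold_spec` used).
#' @export
binarize_vessels <- function(img, baseline, spec = threshold_spec()) {
  g <- global_threshold_large(img, baseline, spec)
  vals <- img$pixels[baseline$mask]
  floor <- mean(vals) + spec$floor_k_noise *
    (if (length(vals) > 1) stats::sd(vals) else 0)
  # exclude the (slightly dilated) trunks and their halo from the local mean
  all_map <- adaptive_threshold_all(img, spec,
                                    exclude = dilate_cpp(g$map, 2L),
                                    floor = floor)
  large_map <- g$map & all_map
  structure(
    list(all_map = all_map, large_map = large_map,
         small_map = subtract_maps(all_map, large_map),
         threshold_global = g$threshold, provenance = spec),
    class = "vessel_maps")
}

#' @export
print.vessel_maps <- function(x, ...) {
  n <- length(x$all_map)
  cat(sprintf(
    "vessel_maps: all %.1f%%, large %.1f%%, small %.1f%% of %d px (global thr %.2f)\n",
    100 * sum(x$all_map) / n, 100 * sum(x$large_map) / n,
    100 * sum(x$small_map) / n, n, x$threshold_global))
  invisible(x)
}
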