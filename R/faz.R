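#' Parameters of the FAZ boundary detector
#'
#' The foveal avascular zone (FAZ) boundary is found by a two-way combined
#' method: a Canny edge detector marks candidate boundary pixels, and a
#' region-based (Chan-Vese-style) level set, initialized as a small disc at
#' the image center, grows over the dark avascular region until it is
#' stopped by the edge map or converges. Defaults were tuned on synthetic
#' phantoms at a 1024-px / 3-mm working grid and are fully overridable.
#'
#' @param canny_sigma Gaussian pre-smoothing sigma for the edge detector,
#'   in pixels at working resolution (default 2).
#' @param canny_low,canny_high hysteresis thresholds as fractions of the
#'   maximum gradient magnitude, `0 < low < high <= 1` (defaults 0.1, 0.2).
#' @param max_iterations level-set iteration cap (default 500).
#' @param smoothing number of morphological curvature-smoothing passes per
#'   iteration (default 1).
#' @param init_radius_mm radius of the initial disc, mm (default 0.2 —
#'   comfortably inside a typical FAZ, which spans roughly 0.2-0.45 mm in
#'   radius; scans are fovea-centered so the field center is a safe seed).
#' @return A list of class `level_set_params`.
#' @export
level_set_params <- function(canny_sigma = 2, canny_low = 0.1,
                             canny_high = 0.2, max_iterations = 500L,
                             smoothing = 1L, init_radius_mm = 0.2) {
  if (!(canny_low < canny_high))
    stop("canny_low must be smaller than canny_high")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (smoothing < 0) stop("smoothing must be non-negative")
  structure(list(canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high,
                 max_iterations = as.integer(max_iterations),
                 smoothing = as.integer(smoothing),
                 init_radius_mm = init_radius_mm),
            class = "level_set_params")
}

#' Canny edge map of an en-face image
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis thresholding. Thresholds are relative to the image's maximum
#' gradient magnitude, so the map is invariant to global intensity scaling.
#' Deterministic for fixed input and parameters.
#'
#' @param img an [enface_image()] at working resolution.
#' @param params a [level_set_params()].
#' @return A logical matrix of edge pixels, congruent with the image.
#' @export
canny_edges <- function(img, params = level_set_params()) {
  stopifnot(inherits(img, "enface_image"))
  canny_cpp(img$pixels, params$canny_sigma, params$canny_low,
            params$canny_high)
}

#' Detect the foveal avascular zone boundary
#'
#' Runs the combined Canny + level-set segmentation (see
#' [level_set_params()]). The evolving region is initialized as a disc of
#' `init_radius_mm` at the image center; edge pixels act as a hard stopping
#' set for the front. After convergence the connected component containing
#' the seed is kept and edge pixels adjacent to it are annexed (the
#' morphological front halts one pixel short of the gradient edge, so the
#' barrier pixels on its boundary belong to the FAZ rim).
#'
#' A result is rejected as "no plausible FAZ" when the region touches the
#' image border, exceeds 25% of the field, vanishes, or shows no intensity
#' contrast against its immediate surround (the FAZ is an avascular, hence
#' dark, zone; a segmentation whose interior is not darker than the
#' surrounding perfused tissue is a failure, as in a non-foveal or fully
#' vascularized image).
#'
#' @param img an [enface_image()] at working resolution (>= 512 px).
#' @param params a [level_set_params()].
#' @return A list of class `faz_boundary`: `contour` (closed polygon,
#'   n x 2 matrix of continuous pixel coordinates), `centroid_px`,
#'   `area_mm2`, `mask` (logical matrix), `converged`, `iterations_used`.
#' @export
detect_faz <- function(img, params = level_set_params()) {
  stopifnot(inherits(img, "enface_image"))
  if (img$width_px < 512)
    stop("detect_faz requires a working resolution of at least 512 px; ",
         "upsample first")
  edges <- canny_edges(img, params)
  center <- image_center_px(img)
  init <- make_disc_mask(img, center, params$init_radius_mm)$mask
  res <- morph_acwe_cpp(img$pixels, init, edges,
                        params$max_iterations, params$smoothing)
  u <- res$mask
  if (res$border_touch)
    stop("no plausible FAZ: region reached the image border")
  # keep the component that contains the seed point
  lab <- label_components_cpp(u, 8L)
  seed_lab <- lab[round(center[2] + 0.5), round(center[1] + 0.5)]
  if (seed_lab == 0) {
    sizes <- tabulate(lab)
    if (length(sizes) == 0 || max(sizes) == 0)
      stop("no plausible FAZ: segmentation collapsed to the empty region")
    seed_lab <- which.max(sizes)
  }
  u <- lab == seed_lab
  # annex rim (edge-barrier) pixels adjacent to the region
  u <- u | (dilate_cpp(u, 1L) & edges)
  n_px <- sum(u)
  if (n_px / length(u) > 0.25)
    stop("no plausible FAZ: region exceeds 25% of the field")
  if (any(u[1, ]) || any(u[nrow(u), ]) || any(u[, 1]) || any(u[, ncol(u)]))
    stop("no plausible FAZ: region reached the image border")
  if (n_px / img$px_per_mm^2 < 0.05)
    stop("no plausible FAZ: region smaller than 0.05 mm^2")
  # contrast check against a surrounding band
  band <- dilate_cpp(u, 6L) & !u
  if (mean(img$pixels[u]) + 5 >= mean(img$pixels[band]))
    stop("no plausible FAZ: interior is not darker than its surround")
  # an avascular zone is homogeneous: its interior carries no edges
  core <- !dilate_cpp(!u, 2L)
  if (sum(core) > 0 && mean(edges[core]) > 0.05)
    stop("no plausible FAZ: interior is edge-dense, not avascular")
  # centroid of the region in continuous pixel coordinates
  idx <- which(u, arr.ind = TRUE)
  centroid <- c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5)
  contour <- faz_contour(u)
  structure(
    list(contour = contour, centroid_px = centroid,
         area_mm2 = n_px / img$px_per_mm^2, mask = u,
         converged = isTRUE(res$converged),
         iterations_used = res$iterations),
    class = "faz_boundary")
}

# longest closed 0.5-level contour of a binary mask, as continuous pixel
# coordinates (x, y)
faz_contour <- function(u) {
  h <- nrow(u); w <- ncol(u)
  cl <- grDevices::contourLines(x = seq_len(w) - 0.5, y = seq_len(h) - 0.5,
                                z = t(u * 1), levels = 0.5)
  if (length(cl) == 0) return(matrix(numeric(0), ncol = 2))
  lens <- vapply(cl, function(p) length(p$x), integer(1))
  p <- cl[[which.max(lens)]]
  cbind(x = p$x, y = p$y)
}

#' @export
print.faz_boundary <- function(x, ...) {
  cat(sprintf(
    "faz_boundary: area %.4f mm2, centroid (%.1f, %.1f) px, %s in %d iters\n",
    x$area_mm2, x$centroid_px[1], x$centroid_px[2],
    if (x$converged) "converged" else "iteration cap hit",
    x$iterations_used))
  invisible(x)
}

#' Fixed-diameter noise-baseline disc at the FAZ centroid
#'
#' The avascular center of the fovea carries no flow signal, so a disc of
#' fixed diameter (0.6 mm by default) centered on the detected FAZ centroid
#' samples pure background/noise. Its intensity statistics set the global
#' threshold for large-vessel binarization. The disc diameter is fixed
#' regardless of the detected FAZ extent; if the disc is not fully contained
#' in the detected FAZ region a warning is raised (baseline pixels then
#' include some perfused tissue).
#'
#' @param faz a converged [detect_faz()] result.
#' @param img the [enface_image()] the FAZ was detected on.
#' @param diameter_mm baseline disc diameter in mm (default 0.6).
#' @return A `region_mask` disc.
#' @export
noise_baseline_disc <- function(faz, img, diameter_mm = 0.6) {
  stopifnot(inherits(faz, "faz_boundary"))
  if (!isTRUE(faz$converged))
    stop("noise_baseline_disc requires a converged FAZ boundary")
  disc <- make_disc_mask(img, faz$centroid_px, diameter_mm / 2)
  if (any(disc$mask & !faz$mask))
    warning("the fixed ", diameter_mm,
            " mm baseline disc is not fully inside the detected FAZ")
  disc
}
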