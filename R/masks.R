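#' Region masks over an en-face image
#'
#' Circular and annular analysis regions are represented as logical matrices
#' congruent with the image, plus descriptor metadata. The geometric
#' convention is fixed so pixel counts are bit-stable: coordinates are
#' 0-based with the origin at the top-left corner, a pixel is a unit square
#' whose center for column `i`, row `j` is `(i + 0.5, j + 0.5)`, and a pixel
#' belongs to a disc iff the distance from the disc center to the pixel
#' center is `<=` the radius (inclusive).
#'
#' @name region_masks
NULL

new_region_mask <- function(mask, descriptor, center_px,
                            inner_radius_mm = NA_real_,
                            outer_radius_mm = NA_real_) {
  structure(
    list(mask = mask, descriptor = descriptor, center_px = center_px,
         inner_radius_mm = inner_radius_mm,
         outer_radius_mm = outer_radius_mm),
    class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask (%s): %d of %d px", x$descriptor,
              sum(x$mask), length(x$mask)))
  if (!is.na(x$outer_radius_mm))
    cat(sprintf(", r = [%s, %.3f] mm",
                if (is.na(x$inner_radius_mm)) "0"
                else sprintf("%.3f", x$inner_radius_mm),
                x$outer_radius_mm))
  cat(sprintf(", center (%.1f, %.1f) px\n", x$center_px[1], x$center_px[2]))
  invisible(x)
}

# squared distance from (cx, cy) to every pixel center, as a matrix
pixel_dist2 <- function(h, w, center_px) {
  xs <- (seq_len(w) - 0.5) - center_px[1]
  ys <- (seq_len(h) - 0.5) - center_px[2]
  outer(ys^2, xs^2, `+`)
}

#' Image center in continuous pixel coordinates
#'
#' @param img an [enface_image()].
#' @return `c(x, y)` of the field center in the 0-based pixel-center
#'   convention (e.g. `c(512, 512)` for a 1024-px image).
#' @export
image_center_px <- function(img) {
  c(img$width_px / 2, img$height_px / 2)
}

#' Circular analysis mask
#'
#' Builds the disc of a given physical radius, e.g. the fixed 0.6 mm
#' diameter foveal disc used as the noise baseline and as the excluded
#' center of the density zone.
#'
#' @param img an [enface_image()] supplying shape and calibration.
#' @param center_px disc center `c(x, y)` in continuous pixel coordinates
#'   (default: image center).
#' @param radius_mm disc radius in mm; must be positive and the disc must
#'   lie fully inside the field.
#' @return A `region_mask` with descriptor `"disc"`.
#' @export
make_disc_mask <- function(img, center_px = image_center_px(img), radius_mm) {
  stopifnot(inherits(img, "enface_image"))
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || radius_mm <= 0)
    stop("radius_mm must be a positive scalar")
  if (center_px[1] < 0 || center_px[1] > img$width_px ||
      center_px[2] < 0 || center_px[2] > img$height_px)
    stop("center_px lies outside the image")
  r_px <- radius_mm * img$px_per_mm
  if (center_px[1] - r_px < 0 || center_px[1] + r_px > img$width_px ||
      center_px[2] - r_px < 0 || center_px[2] + r_px > img$height_px)
    stop(sprintf(
      "disc of radius %.3f mm at (%.1f, %.1f) extends beyond the %d-px field",
      radius_mm, center_px[1], center_px[2], img$width_px))
  d2 <- pixel_dist2(img$height_px, img$width_px, center_px)
  new_region_mask(d2 <= r_px^2, "disc", center_px,
                  outer_radius_mm = radius_mm)
}

#' Annular analysis mask
#'
#' The density zone of the pipeline: a 2.5 mm diameter macular zone with the
#' central 0.6 mm foveal disc excluded, i.e. the annulus between
#' `inner_radius_mm` and `outer_radius_mm`.
#'
#' @inheritParams make_disc_mask
#' @param inner_radius_mm inner (excluded) radius in mm, default 0.3.
#' @param outer_radius_mm outer radius in mm, default 1.25.
#' @return A `region_mask` with descriptor `"annulus"`.
#' @export
make_annulus_mask <- function(img, center_px = image_center_px(img),
                              inner_radius_mm = 0.3,
                              outer_radius_mm = 1.25) {
  if (!(inner_radius_mm > 0))
    stop("inner_radius_mm must be positive")
  if (inner_radius_mm >= outer_radius_mm)
    stop("inner_radius_mm must be smaller than outer_radius_mm")
  outer <- make_disc_mask(img, center_px, outer_radius_mm)
  r_in <- inner_radius_mm * img$px_per_mm
  d2 <- pixel_dist2(img$height_px, img$width_px, center_px)
  new_region_mask(outer$mask & (d2 > r_in^2), "annulus", center_px,
                  inner_radius_mm = inner_radius_mm,
                  outer_radius_mm = outer_radius_mm)
}
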