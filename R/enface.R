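#' En-face OCT-A image container
#'
#' An `enface_image` holds an en-face angiogram as a numeric matrix of
#' grayscale intensities on the 8-bit scale `[0, 255]` together with its
#' physical calibration. OCT-A scans of the macula are square acquisitions
#' (nominally 3 x 3 mm centered on the fovea), so width and height are
#' expected to agree; a non-square image is accepted with a warning and the
#' width is used for calibration.
#'
#' Intensities may be non-integer (e.g. after interpolation): values are kept
#' as 8-bit-scaled reals, clipped to `[0, 255]` but not re-quantized, to
#' avoid banding artifacts ahead of thresholding.
#'
#' @param pixels numeric matrix, row = image row, column = image column,
#'   values in `[0, 255]`.
#' @param extent_mm physical side length of the field in mm (default 3).
#' @param layer capillary slab tag: `"SRCL"` (superficial), `"DRCL"` (deep)
#'   or `"unknown"`. Carried as metadata; it selects the vessel map used by
#'   [quantify_image()].
#' @param source_id free-text provenance (file name for loaded images).
#' @return An object of class `enface_image` with fields `pixels`,
#'   `width_px`, `height_px`, `extent_mm`, `layer`, `source_id` and the
#'   derived calibration `px_per_mm = width_px / extent_mm`.
#' @export
enface_image <- function(pixels, extent_mm = 3.0, layer = "unknown",
                         source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  if (!layer %in% c("SRCL", "DRCL", "unknown"))
    stop("layer must be one of 'SRCL', 'DRCL', 'unknown'")
  if (!is.numeric(extent_mm) || length(extent_mm) != 1 || extent_mm <= 0)
    stop("extent_mm must be a positive scalar")
  h <- nrow(pixels); w <- ncol(pixels)
  if (h != w)
    warning("non-square image (", w, " x ", h,
            "); calibration uses the width")
  structure(
    list(pixels = pixels, width_px = w, height_px = h,
         extent_mm = extent_mm, px_per_mm = w / extent_mm,
         layer = layer, source_id = source_id),
    class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf(
    "enface_image: %d x %d px, %.2f mm field (%.2f px/mm), layer %s\n",
    x$width_px, x$height_px, x$extent_mm, x$px_per_mm, x$layer))
  cat(sprintf("  intensity range [%.1f, %.1f]  source: %s\n",
              min(x$pixels), max(x$pixels),
              if (nzchar(x$source_id)) x$source_id else "<in memory>"))
  invisible(x)
}

#' Load an en-face angiogram from a PNG file
#'
#' Reads an 8- or 16-bit grayscale PNG, or an RGB(A) PNG converted to
#' luminance (Rec. 601 weights). Intensities are rescaled to the 8-bit range
#' `[0, 255]`, the scale on which all thresholds in this package operate.
#'
#' @param path path to a PNG file.
#' @inheritParams enface_image
#' @return An [enface_image()] with `source_id` set to the file name.
#' @export
load_enface <- function(path, extent_mm = 3.0, layer = "unknown") {
  if (!file.exists(path))
    stop("cannot read image file: ", path)
  arr <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop("cannot decode PNG '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3)
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    else
      arr <- arr[, , 1]   # gray + alpha
  }
  # readPNG maps the container max to 1.0 for both 8- and 16-bit files
  enface_image(arr * 255, extent_mm = extent_mm, layer = layer,
               source_id = basename(path))
}

#' Write a grayscale or binary image as PNG
#'
#' @param x an [enface_image()] or a numeric/logical matrix. Logical
#'   matrices are written as 0/255 masks.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enface_png <- function(x, path) {
  m <- if (inherits(x, "enface_image")) x$pixels else x
  if (is.logical(m)) m <- m * 255
  png::writePNG(pmin(pmax(m / 255, 0), 1), path)
  invisible(path)
}

#' Upsample an en-face image by bicubic interpolation
#'
#' Raw macular angiograms (304 x 304 A-scans over 3 mm) are extended to a
#' finer working grid before segmentation so that sub-pixel structures — the
#' FAZ rim, capillary edges — are resolved by the edge detector. Bicubic
#' (cubic convolution, a = -0.5) interpolation is used; interpolated values
#' are clipped back to `[0, 255]` but kept as reals.
#'
#' @param img an [enface_image()].
#' @param target_px output side length in pixels; must be at least the
#'   source size (this operation never downsamples).
#' @return An [enface_image()] of size `target_px` with rescaled
#'   calibration (`px_per_mm = target_px / extent_mm`).
#' @export
upsample_bicubic <- function(img, target_px = 1024L) {
  stopifnot(inherits(img, "enface_image"))
  target_px <- as.integer(target_px)
  if (target_px < max(img$width_px, img$height_px))
    stop("target_px (", target_px, ") is smaller than the source (",
         img$width_px, "); downsampling is not supported")
  if (target_px == img$width_px && target_px == img$height_px)
    return(img)
  out <- bicubic_resize_cpp(img$pixels, target_px, target_px)
  out <- pmin(pmax(out, 0), 255)
  enface_image(out, extent_mm = img$extent_mm, layer = img$layer,
               source_id = img$source_id)
}
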