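#' Specification of a synthetic OCT-A phantom
#'
#' Phantoms emulate the structures the quantification pipeline must handle:
#' a central avascular zone (dark, signal-free), a perifoveal terminal
#' capillary ring hugging its boundary (as in the real macula, where the
#' FAZ is bounded by a continuous capillary arcade — this is also what
#' gives the edge detector a well-defined rim), a few large vessels of
#' arteriole/venule caliber arcing across the field while avoiding the
#' fovea, a dense capillary meshwork drawn as persistent random walks, and
#' OCT-typical noise: multiplicative gamma speckle plus additive Gaussian
#' read noise.
#'
#' @param size_px image side in pixels (default 512 — at the default 3 mm
#'   extent this is a >= 512-px working grid the FAZ detector accepts
#'   directly, keeping simulation studies fast).
#' @param extent_mm physical side length, mm.
#' @param faz_shape `"circle"` or `"ellipse"`.
#' @param faz_radii_mm radius (circle) or semi-axes `c(a, b)` (ellipse), mm.
#' @param n_large_vessels number of large vessels (0 for a deep-layer-like
#'   phantom without arteriole/venule trunks).
#' @param large_width_px large-vessel stroke width, px (default 8, about
#'   47 um at 512 px / 3 mm — arteriole caliber).
#' @param capillary_target_density target fraction of the analysis annulus
#'   covered by the capillary truth mask, in (0, 0.9).
#' @param capillary_width_px range `c(min, max)` of capillary stroke
#'   widths, px (default 1, i.e. single-pixel ~18 um strokes at
#'   512 px / 3 mm — true capillary caliber).
#' @param ring_width_px width of the perifoveal ring, px.
#' @param vessel_intensity,capillary_intensity,background_intensity 8-bit
#'   intensities of large-vessel, capillary and background pixels before
#'   noise (defaults 210, 120, 35). Large trunks decorrelate more strongly
#'   than capillaries in OCT-A, so the two vessel classes differ in
#'   brightness as well as caliber; the global noise-baseline threshold
#'   relies on caliber, not on this brightness gap.
#' @param noise_sd additive Gaussian noise SD (default 5).
#' @param speckle_shape shape of the unit-mean multiplicative gamma speckle
#'   (default 30, i.e. about 18% relative speckle contrast; `Inf` disables
#'   speckle for noise-free phantoms).
#' @param seed RNG seed; identical spec + seed gives identical phantoms.
#' @param layer layer tag stamped on the generated image.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size_px = 512L, extent_mm = 3.0,
                         faz_shape = c("circle", "ellipse"),
                         faz_radii_mm = 0.3, n_large_vessels = 4L,
                         large_width_px = 8, capillary_target_density = 0.44,
                         capillary_width_px = c(1, 1), ring_width_px = 2,
                         vessel_intensity = 210, capillary_intensity = 120,
                         background_intensity = 35,
                         noise_sd = 5, speckle_shape = 30, seed = 1L,
                         layer = "SRCL") {
  faz_shape <- match.arg(faz_shape)
  if (faz_shape == "ellipse" && length(faz_radii_mm) != 2)
    stop("an ellipse needs two semi-axes in faz_radii_mm")
  if (any(faz_radii_mm <= 0) || large_width_px <= 0 ||
      any(capillary_width_px <= 0) || vessel_intensity <= 0 ||
      capillary_intensity <= 0 || background_intensity <= 0)
    stop("radii, widths and intensities must be positive")
  if (capillary_target_density <= 0 || capillary_target_density >= 0.9)
    stop("capillary_target_density must lie in (0, 0.9)")
  structure(list(size_px = as.integer(size_px), extent_mm = extent_mm,
                 faz_shape = faz_shape, faz_radii_mm = faz_radii_mm,
                 n_large_vessels = as.integer(n_large_vessels),
                 large_width_px = large_width_px,
                 capillary_target_density = capillary_target_density,
                 capillary_width_px = capillary_width_px,
                 ring_width_px = ring_width_px,
                 vessel_intensity = vessel_intensity,
                 capillary_intensity = capillary_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, speckle_shape = speckle_shape,
                 seed = as.integer(seed), layer = layer),
            class = "phantom_spec")
}

# elliptical/circular FAZ mask in the pixel-center convention
faz_truth_mask <- function(n, center, radii_px) {
  if (length(radii_px) == 1) radii_px <- rep(radii_px, 2)
  xs <- ((seq_len(n) - 0.5) - center[1]) / radii_px[1]
  ys <- ((seq_len(n) - 0.5) - center[2]) / radii_px[2]
  outer(ys^2, xs^2, `+`) <= 1
}

# dense (row, col) samples along the FAZ boundary, just outside it
ring_path <- function(center, radii_px, offset_px) {
  if (length(radii_px) == 1) radii_px <- rep(radii_px, 2)
  a <- radii_px[1] + offset_px; b <- radii_px[2] + offset_px
  n <- ceiling(2 * pi * max(a, b) * 2)
  th <- seq(0, 2 * pi, length.out = n)
  list(rows = center[2] + b * sin(th) + 0.5,
       cols = center[1] + a * cos(th) + 0.5)
}

# a large vessel: quadratic Bezier between two random border points,
# rejected until it stays clear of the foveal center
large_vessel_path <- function(n, center, clear_px) {
  border_point <- function() {
    side <- sample.int(4, 1)
    t <- runif(1, 0, n)
    switch(side, c(t, 1), c(t, n), c(1, t), c(n, t)) # (x, y)
  }
  for (attempt in 1:200) {
    p0 <- border_point(); p2 <- border_point()
    p1 <- c(runif(1, 0.15 * n, 0.85 * n), runif(1, 0.15 * n, 0.85 * n))
    tt <- seq(0, 1, length.out = 3 * n)
    x <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
    y <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
    d <- sqrt((x - center[1])^2 + (y - center[2])^2)
    if (min(d) > clear_px && max(abs(p0 - p2)) > n / 2)
      return(list(rows = y + 0.5, cols = x + 0.5))
  }
  stop("could not place a large vessel clear of the fovea")
}

# one capillary stroke: a persistent random walk
capillary_walk <- function(n, len) {
  start <- runif(2, 1, n)
  th <- runif(1, 0, 2 * pi) + cumsum(rnorm(len, 0, 0.25))
  list(rows = start[2] + cumsum(sin(th)), cols = start[1] + cumsum(cos(th)))
}

#' Generate a synthetic OCT-A phantom with ground truth
#'
#' Draws the structures described in [phantom_spec()] and iterates
#' capillary placement until the capillary truth mask covers the analysis
#' annulus (0.3-1.25 mm around the field center by default geometry) to
#' within 0.5 percentage points of the target density. Deterministic for a
#' fixed spec (seed included).
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom`: `image` (an [enface_image()]),
#'   `truth_large`, `truth_capillary`, `truth_faz` (logical matrices),
#'   `true_zone_density` (capillary fraction of the annulus, in `[0, 1]`),
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  n <- spec$size_px
  px_per_mm <- n / spec$extent_mm
  center <- c(n / 2, n / 2)
  radii_px <- spec$faz_radii_mm * px_per_mm
  truth_faz <- faz_truth_mask(n, center, radii_px)
  # keep-out zone for vessel drawing: FAZ plus a small margin
  keepout <- faz_truth_mask(n, center, radii_px + 0.05 * px_per_mm)

  # analysis annulus used for the density target (standard zone geometry)
  xs <- (seq_len(n) - 0.5) - center[1]
  ys <- (seq_len(n) - 0.5) - center[2]
  d2 <- outer(ys^2, xs^2, `+`)
  annulus <- d2 <= (1.25 * px_per_mm)^2 & d2 > (0.3 * px_per_mm)^2
  n_annulus <- sum(annulus)

  truth_large <- matrix(FALSE, n, n)
  truth_capillary <- matrix(FALSE, n, n)

  # perifoveal terminal ring, hugging the outside of the FAZ boundary
  rp <- ring_path(center, radii_px, spec$ring_width_px / 2 + 0.5)
  stamp_discs_cpp(truth_capillary, rp$rows, rp$cols,
                  spec$ring_width_px / 2, annulus)

  if (spec$n_large_vessels > 0) {
    clear_px <- max(radii_px) + 0.15 * px_per_mm
    for (i in seq_len(spec$n_large_vessels)) {
      lv <- large_vessel_path(n, center, clear_px)
      stamp_discs_cpp(truth_large, lv$rows, lv$cols,
                      spec$large_width_px / 2, annulus)
    }
  }

  # capillary meshwork: add walks until the annulus density hits target.
  # Strokes never overwrite trunks: in the 2-D projection a crossing
  # capillary is occluded by the large vessel, so trunk pixels are not
  # capillary truth and do not count toward the density target.
  stamp_region <- annulus & !truth_large
  target_n <- spec$capillary_target_density * n_annulus
  tol_n <- 0.004 * n_annulus            # stop inside +-0.5 points
  cur <- sum(truth_capillary & stamp_region)
  attempts <- 0L
  cur_checkpoint <- cur
  wmin <- min(spec$capillary_width_px); wmax <- max(spec$capillary_width_px)
  while (cur < target_n - tol_n) {
    attempts <- attempts + 1L
    # saturation check: if 2000 further strokes add almost nothing, the
    # target cannot be reached with this width budget
    if (attempts %% 2000L == 0L) {
      if (cur - cur_checkpoint < 5e-4 * n_annulus || attempts > 30000L)
        stop("capillary_target_density ", spec$capillary_target_density,
             " is unreachable for this width budget")
      cur_checkpoint <- cur
    }
    near <- (target_n - cur) < 0.015 * n_annulus
    len <- if (near) 20L else sample(40:120, 1)
    w <- if (near) wmin else runif(1, wmin, wmax)
    wk <- capillary_walk(n, len)
    keep <- wk$rows >= 1 & wk$rows <= n & wk$cols >= 1 & wk$cols <= n
    if (any(keep)) {
      ir <- pmin(pmax(round(wk$rows[keep]), 1), n)
      ic <- pmin(pmax(round(wk$cols[keep]), 1), n)
      keep2 <- !keepout[cbind(ir, ic)] & !truth_large[cbind(ir, ic)]
      if (any(keep2))
        cur <- cur + stamp_discs_cpp(truth_capillary, wk$rows[keep][keep2],
                                     wk$cols[keep][keep2], w / 2,
                                     stamp_region)
    }
  }

  # construction invariants: the avascular zone is vessel-free, and
  # capillary truth never overlaps trunk truth (occlusion)
  truth_capillary[truth_faz] <- FALSE
  truth_large[truth_faz] <- FALSE
  truth_capillary[truth_large] <- FALSE

  clean <- matrix(spec$background_intensity, n, n)
  clean[truth_capillary] <- spec$capillary_intensity
  clean[truth_large] <- spec$vessel_intensity
  clean <- gaussian_blur_cpp(clean, 0.5)
  img <- clean
  if (is.finite(spec$speckle_shape))
    img <- img * rgamma(n * n, shape = spec$speckle_shape,
                        rate = spec$speckle_shape)
  if (spec$noise_sd > 0)
    img <- img + rnorm(n * n, 0, spec$noise_sd)
  img <- matrix(pmin(pmax(img, 0), 255), n, n)

  structure(
    list(image = enface_image(img, extent_mm = spec$extent_mm,
                              layer = spec$layer,
                              source_id = sprintf("phantom-seed%d", spec$seed)),
         truth_large = truth_large, truth_capillary = truth_capillary,
         truth_faz = truth_faz,
         true_zone_density = sum(truth_capillary & annulus) / n_annulus,
         spec = spec),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "phantom: %d px, FAZ %s %.2f mm, zone capillary density %.3f (target %.3f)\n",
    x$spec$size_px, x$spec$faz_shape,
    max(x$spec$faz_radii_mm), x$true_zone_density,
    x$spec$capillary_target_density))
  invisible(x)
}

#' Dice overlap between two binary maps
#'
#' `2|A & B| / (|A| + |B|)`; 1 for two empty maps by convention.
#'
#' @param a,b congruent logical matrices.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
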