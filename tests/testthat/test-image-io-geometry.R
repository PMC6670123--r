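test_that("PNG loading handles 8-bit, RGB, 16-bit and degenerate inputs", {
  # 304 x 304 like a raw scan: calibration follows from width / extent
  m <- matrix(round(seq(0, 255, length.out = 304 * 304)), 304, 304)
  img <- load_enface(write_png8(m), extent_mm = 3.0, layer = "SRCL")
  expect_s3_class(img, "enface_image")
  expect_equal(img$px_per_mm, 304 / 3, tolerance = 1e-12)
  expect_equal(img$layer, "SRCL")
  expect_equal(max(abs(img$pixels - m)), 0)

  # all-zero image round-trips to all-zero
  z <- load_enface(write_png8(matrix(0, 64, 64)))
  expect_identical(range(z$pixels), c(0, 0))

  # RGB is converted to luminance with Rec. 601 weights
  arr <- array(0, dim = c(32, 32, 3))
  arr[, , 1] <- 1
  p <- tempfile(fileext = ".png")
  png::writePNG(arr, p)
  rgb <- load_enface(p)
  expect_equal(rgb$pixels[1, 1], 0.299 * 255, tolerance = 1e-6)

  # 16-bit: intensities rescaled onto [0, 255], container max maps to 255
  m16 <- matrix(as.integer(seq(0, 65535, length.out = 48 * 48)), 48, 48)
  img16 <- load_enface(write_png16(m16))
  expect_equal(max(img16$pixels), 255)
  # oracle: direct rescale of the 16-bit samples
  expect_equal(img16$pixels, m16 / 257, tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(load_enface(tempfile(fileext = ".png")), "cannot read")
  notpng <- tempfile(fileext = ".png")
  writeLines("not a png", notpng)
  expect_error(load_enface(notpng), "cannot decode")
  expect_warning(enface_image(matrix(0, 10, 20)), "non-square")
})

test_that("bicubic upsampling preserves constants, ramps and calibration", {
  const <- enface_image(matrix(37, 304, 304))
  up <- upsample_bicubic(const, 1024L)
  expect_equal(up$width_px, 1024L)
  expect_equal(up$px_per_mm, 1024 / 3, tolerance = 1e-12)
  expect_equal(range(up$pixels), c(37, 37), tolerance = 1e-9)

  # linear horizontal ramp is reproduced away from the borders
  v <- seq(10, 240, length.out = 128)
  ramp <- enface_image(matrix(v, 128, 128, byrow = TRUE))
  upr <- upsample_bicubic(ramp, 512L)
  # analytic ramp at output pixel centers (mapped back to source coords)
  xs <- (seq_len(512) - 0.5) * 128 / 512 - 0.5
  expected <- 10 + (240 - 10) * xs / 127
  interior <- 17:496
  diffs <- sweep(upr$pixels[interior, interior, drop = FALSE], 2,
                 expected[interior])
  expect_lt(max(abs(diffs)), 1)
  # global mean preserved on a smooth image
  smooth <- enface_image(
    127 + 100 * outer(sin(seq(0, pi, length.out = 128)),
                      cos(seq(0, pi, length.out = 128))) / 2)
  ups <- upsample_bicubic(smooth, 512L)
  expect_lt(abs(mean(ups$pixels) - mean(smooth$pixels)), 0.5)

  expect_error(upsample_bicubic(const, 100L), "downsampling")
  # equal size is the identity
  expect_identical(upsample_bicubic(const, 304L), const)
})

test_that("disc masks match analytic areas and reject bad geometry", {
  img <- enface_image(matrix(0, 1024, 1024))
  d <- make_disc_mask(img, radius_mm = 0.3)
  r_px <- 0.3 * 1024 / 3
  expect_lt(abs(sum(d$mask) - pi * r_px^2) / (pi * r_px^2), 0.002)

  # area convergence: 1% at modest radii, 0.2% at large radii
  small <- enface_image(matrix(0, 256, 256))
  d2 <- make_disc_mask(small, radius_mm = 0.25)  # ~21 px radius
  r2 <- 0.25 * 256 / 3
  expect_lt(abs(sum(d2$mask) - pi * r2^2) / (pi * r2^2), 0.01)

  expect_error(make_disc_mask(img, radius_mm = 0), "positive")
  expect_error(make_disc_mask(img, radius_mm = 1.6), "beyond")
  expect_error(make_disc_mask(img, center_px = c(-5, 500), radius_mm = 0.1),
               "outside")
  # deterministic reconstruction
  expect_identical(d$mask, make_disc_mask(img, radius_mm = 0.3)$mask)
})

test_that("annulus masks are outer disc minus inner disc", {
  img <- enface_image(matrix(0, 1024, 1024))
  a <- make_annulus_mask(img)
  ppm <- 1024 / 3
  analytic <- pi * ((1.25 * ppm)^2 - (0.3 * ppm)^2)
  expect_lt(abs(sum(a$mask) - analytic) / analytic, 0.01)
  expect_equal(sum(a$mask), 539008)  # frozen: bit-stable geometry

  inner <- make_disc_mask(img, radius_mm = 0.3)
  expect_false(any(a$mask & inner$mask))
  outer_d <- make_disc_mask(img, radius_mm = 1.25)
  expect_identical(a$mask | inner$mask, outer_d$mask)

  expect_error(make_annulus_mask(img, inner_radius_mm = 0.5,
                                 outer_radius_mm = 0.5), "smaller")
  expect_error(make_annulus_mask(img, inner_radius_mm = 0), "positive")
})
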