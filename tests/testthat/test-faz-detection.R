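test_that("canny edge map: empty on constants, concentrated on the FAZ rim", {
  const <- enface_image(matrix(128, 512, 512))
  expect_false(any(canny_edges(const)))

  ph <- default_phantom(2)
  edges <- canny_edges(ph$image)
  # rim coverage: walk the true FAZ circle, count points with an edge
  # within 3 px
  near <- octarcd:::dilate_cpp(edges, 3L)
  r_px <- 0.3 * 512 / 3
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  xs <- round(256 + r_px * cos(th) + 0.5)
  ys <- round(256 + r_px * sin(th) + 0.5)
  expect_gt(mean(near[cbind(ys, xs)]), 0.8)

  # robustness: extra i.i.d. noise of SD 5 moves the edge count < 30%
  noisy <- enface_image(pmin(pmax(
    ph$image$pixels + withr::with_seed(9, rnorm(512^2, 0, 5)), 0), 255))
  n0 <- sum(edges)
  n1 <- sum(canny_edges(noisy))
  expect_lt(abs(n1 - n0) / n0, 0.3)
})

test_that("FAZ detection recovers circular and elliptical zones", {
  ph <- default_phantom(3)
  faz <- detect_faz(ph$image)
  truth <- pi * 0.3^2
  expect_true(faz$converged)
  expect_lt(abs(faz$area_mm2 - truth) / truth, 0.1)
  # centroid within 0.05 mm of the true center
  ppm <- 512 / 3
  expect_lt(sqrt(sum((faz$centroid_px - c(256, 256))^2)) / ppm, 0.05)
  # contour is closed and the centroid lies inside it
  expect_gt(nrow(faz$contour), 10)
  expect_equal(faz$contour[1, ], faz$contour[nrow(faz$contour), ])

  ell <- generate_phantom(phantom_spec(seed = 5, faz_shape = "ellipse",
                                       faz_radii_mm = c(0.25, 0.35)))
  fe <- detect_faz(ell$image)
  truth_e <- pi * 0.25 * 0.35
  expect_lt(abs(fe$area_mm2 - truth_e) / truth_e, 0.1)
})

test_that("detection is deterministic and errors without a plausible FAZ", {
  ph <- default_phantom(4)
  f1 <- detect_faz(ph$image)
  f2 <- detect_faz(ph$image)
  expect_identical(f1$mask, f2$mask)
  expect_identical(f1$contour, f2$contour)

  # fully vascularized field: mesh everywhere, no avascular zone
  vasc <- generate_phantom(phantom_spec(seed = 7, faz_radii_mm = 0.02,
                                        ring_width_px = 0.5))
  expect_error(detect_faz(vasc$image), "no plausible FAZ")

  small <- enface_image(matrix(0, 256, 256))
  expect_error(detect_faz(small), "at least 512")
})

test_that("enlarging the true avascular zone never shrinks the detection", {
  areas <- vapply(c(0.22, 0.30, 0.38), function(r) {
    ph <- generate_phantom(phantom_spec(seed = 21, faz_radii_mm = r,
                                        noise_sd = 0, speckle_shape = Inf))
    detect_faz(ph$image)$area_mm2
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("the noise-baseline disc is fixed-diameter at the FAZ centroid", {
  ph <- default_phantom(2)
  work <- ph$image
  faz <- detect_faz(work)
  disc <- suppressWarnings(noise_baseline_disc(faz, work))
  r_px <- 0.3 * work$px_per_mm
  expect_lt(abs(sum(disc$mask) - pi * r_px^2) / (pi * r_px^2), 0.01)

  # FAZ narrower than 0.6 mm: still the fixed disc, with a warning
  nf <- generate_phantom(phantom_spec(seed = 8, faz_radii_mm = 0.22))
  faz_n <- detect_faz(nf$image)
  expect_warning(d2 <- noise_baseline_disc(faz_n, nf$image),
                 "not fully inside")
  expect_lt(abs(sum(d2$mask) - pi * r_px^2) / (pi * r_px^2), 0.01)

  # baseline disc is a subset of the 2.5 mm zone disc by construction
  zone_disc <- make_disc_mask(work, faz$centroid_px, 1.25)
  expect_false(any(disc$mask & !zone_disc$mask))

  faz_bad <- faz
  faz_bad$converged <- FALSE
  expect_error(noise_baseline_disc(faz_bad, work), "converged")
})
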