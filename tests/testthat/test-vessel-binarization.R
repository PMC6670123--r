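test_that("global threshold follows the baseline mean + k * SD formula", {
  # all-equal baseline: zero SD, threshold is the mean, with a warning
  img <- enface_image(matrix(10, 128, 128))
  base <- make_disc_mask(img, radius_mm = 0.4)
  expect_warning(g <- global_threshold_large(img, base,
                                             threshold_spec(k_noise = 2)),
                 "SD is zero")
  expect_equal(g$threshold, 10)
  expect_false(any(g$map))  # nothing strictly above the threshold

  # sampled baseline: threshold close to mean + 2 SD of the population
  px <- withr::with_seed(1, matrix(rnorm(512^2, 10, 2), 512, 512))
  img2 <- enface_image(pmin(pmax(px, 0), 255))
  base2 <- make_disc_mask(img2, radius_mm = 0.6)  # ~33k px
  g2 <- global_threshold_large(img2, base2, threshold_spec(k_noise = 2))
  expect_lt(abs(g2$threshold - 14), 0.1)
})

test_that("large-vessel purification separates calibers on phantoms", {
  ph <- default_phantom(1)
  q <- default_quant(1)
  maps <- attr(q, "maps")
  expect_gt(dice(maps$large_map, ph$truth_large), 0.8)
  # large map covers < 10% of true capillary pixels
  expect_lt(sum(maps$large_map & ph$truth_capillary) /
              sum(ph$truth_capillary), 0.1)
})

test_that("adaptive threshold: empty on constants, Dice floor on phantoms", {
  img <- enface_image(matrix(77, 256, 256))
  expect_false(any(adaptive_threshold_all(img, threshold_spec())))

  ph <- default_phantom(1)
  maps <- attr(default_quant(1), "maps")
  expect_gt(dice(maps$all_map, ph$truth_capillary | ph$truth_large), 0.7)

  expect_error(
    adaptive_threshold_all(enface_image(matrix(0, 32, 32)),
                           threshold_spec(adaptive_window_px = 51L)),
    "larger than the image")

  # despeckling is monotone in the size cut
  noisy <- enface_image(pmin(pmax(withr::with_seed(
    4, matrix(rnorm(256^2, 100, 40), 256, 256)), 0), 255))
  n0 <- sum(adaptive_threshold_all(noisy, threshold_spec(min_object_px = 0)))
  n10 <- sum(adaptive_threshold_all(noisy, threshold_spec(min_object_px = 10)))
  expect_lte(n10, n0)
})

test_that("map subtraction obeys its set identities", {
  withr::with_seed(11, {
    for (i in 1:25) {
      all_map <- matrix(runif(256) < 0.5, 16, 16)
      large <- matrix(runif(256) < 0.3, 16, 16) & all_map
      small <- subtract_maps(all_map, large)
      expect_identical(small, all_map & !large)
      # pixel conservation
      expect_identical(sum(small) + sum(all_map & large), sum(all_map))
    }
  })
  expect_identical(subtract_maps(matrix(TRUE, 4, 4), matrix(FALSE, 4, 4)),
                   matrix(TRUE, 4, 4))
  expect_false(any(subtract_maps(matrix(TRUE, 4, 4), matrix(TRUE, 4, 4))))
  expect_error(subtract_maps(matrix(TRUE, 4, 4), matrix(TRUE, 5, 5)),
               "shapes")
})

test_that("binarization is covariant under global intensity scaling", {
  ph <- default_phantom(6)
  img <- ph$image
  faz <- detect_faz(img)
  base <- suppressWarnings(noise_baseline_disc(faz, img))
  spec <- threshold_spec(adaptive_offset = 0, adaptive_window_px = 51L,
                         min_object_px = 5L, min_width_px = 4)
  m1 <- binarize_vessels(img, base, spec)
  scaled <- enface_image(img$pixels * 0.5, extent_mm = img$extent_mm)
  m2 <- binarize_vessels(scaled, base, spec)
  expect_identical(m1$all_map, m2$all_map)
  expect_identical(m1$large_map, m2$large_map)
  expect_equal(m2$threshold_global, m1$threshold_global * 0.5)
})

test_that("vessel_maps invariants hold on a full phantom run", {
  maps <- attr(default_quant(2), "maps")
  expect_identical(maps$small_map, maps$all_map & !maps$large_map)
  expect_false(any(maps$large_map & !maps$all_map))  # harmonized subset
  expect_identical(sum(maps$small_map) + sum(maps$all_map & maps$large_map),
                   sum(maps$all_map))
})
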