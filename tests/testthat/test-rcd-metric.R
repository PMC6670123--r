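test_that("compute_rcd is an exact pixel proportion", {
  img <- enface_image(matrix(0, 512, 512))
  zone <- make_annulus_mask(img)
  full <- compute_rcd(matrix(TRUE, 512, 512), zone)
  expect_equal(full$rcd_percent, 100)
  empty <- compute_rcd(matrix(FALSE, 512, 512), zone)
  expect_equal(empty$rcd_percent, 0)

  # checkerboard: half the zone, up to one pixel's worth
  cb <- outer(seq_len(512), seq_len(512), function(i, j) (i + j) %% 2 == 1)
  half <- compute_rcd(cb, zone)
  expect_equal(half$rcd_percent, 50, tolerance = 0.05)
  expect_equal(half$rcd_percent,
               100 * half$n_vessel_px / half$n_zone_px)

  bad_zone <- zone
  bad_zone$mask <- matrix(FALSE, 512, 512)
  expect_error(compute_rcd(cb, bad_zone), "empty")
  expect_error(compute_rcd(matrix(TRUE, 4, 4), zone), "shapes")
})

test_that("deleting vessel pixels never increases the density", {
  zone <- make_annulus_mask(enface_image(matrix(0, 256, 256)))
  withr::with_seed(3, {
    m <- matrix(runif(256^2) < 0.4, 256, 256)
    prev <- compute_rcd(m, zone)$rcd_percent
    for (i in 1:5) {
      m[m & matrix(runif(256^2) < 0.2, 256, 256)] <- FALSE
      cur <- compute_rcd(m, zone)$rcd_percent
      expect_lte(cur, prev)
      prev <- cur
    }
  })
})

test_that("FAZ-disc pixels never contribute to the density", {
  ph <- default_phantom(2)
  q <- default_quant(2)
  faz <- attr(q, "faz")
  inner <- make_disc_mask(ph$image, faz$centroid_px, 0.3)
  zone <- make_annulus_mask(ph$image, faz$centroid_px)
  expect_false(any(zone$mask & inner$mask))
  # saturating the foveal disc does not change the result
  maps <- attr(q, "maps")
  flooded <- maps$small_map | inner$mask
  expect_equal(compute_rcd(flooded, zone)$rcd_percent,
               compute_rcd(maps$small_map, zone)$rcd_percent)
})

test_that("end-to-end density recovery on superficial-layer phantoms", {
  for (s in 1:3) {
    ph <- default_phantom(s)
    q <- default_quant(s)
    expect_lt(abs(q$rcd_percent - 100 * ph$true_zone_density), 3)
    expect_equal(q$layer, "SRCL")
    expect_false(is.na(q$faz_area_mm2))
  }
})

test_that("erasing capillaries leaves only a small large-vessel leak", {
  ph <- default_phantom(2)
  spec <- ph$spec
  # re-render the same phantom with capillaries at background intensity
  bare <- generate_phantom(phantom_spec(
    seed = spec$seed, capillary_intensity = spec$background_intensity,
    vessel_intensity = spec$vessel_intensity))
  # without capillaries there is no rim to detect; supply the true FAZ
  q <- suppressWarnings(quantify_image(bare$image, layer = "SRCL",
                                       config = test_config(),
                                       faz_mask = bare$truth_faz))
  expect_lte(q$rcd_percent, 2)
})

test_that("deep-layer mode equals superficial mode without large vessels", {
  ph <- generate_phantom(phantom_spec(seed = 11, n_large_vessels = 0L,
                                      layer = "DRCL"))
  qs <- suppressWarnings(quantify_image(ph$image, layer = "SRCL",
                                        config = test_config()))
  qd <- suppressWarnings(quantify_image(ph$image, layer = "DRCL",
                                        config = test_config()))
  expect_lt(abs(qs$rcd_percent - qd$rcd_percent), 0.5)
})

test_that("a user-supplied FAZ mask bypasses detection", {
  ph <- default_phantom(1)
  truth_mask <- ph$truth_faz
  q <- suppressWarnings(quantify_image(ph$image, layer = "SRCL",
                                       config = test_config(),
                                       faz_mask = truth_mask))
  expect_equal(q$faz_area_mm2, sum(truth_mask) / (512 / 3)^2)
  expect_lt(abs(q$rcd_percent - 100 * ph$true_zone_density), 3)
  expect_error(
    quantify_image(ph$image, layer = "SRCL", config = test_config(),
                   faz_mask = matrix(FALSE, 512, 512)),
    "empty")
})
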