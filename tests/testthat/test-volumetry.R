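test_that("scale factors are the physical side lengths of a resized pixel", {
  expect_equal(scale_factors(c(256, 256), c(256, 256), c(1, 1)),
               c(sfw = 1, sfh = 1))
  expect_equal(scale_factors(c(512, 512), c(256, 256), c(0.5, 0.5)),
               c(sfw = 1, sfh = 1))
  # total in-plane area is conserved: per-pixel area x resized pixel count
  # equals spacing area x original pixel count
  sf <- scale_factors(c(448, 512), c(256, 256), c(0.43, 0.43))
  expect_equal(sf[["sfw"]] * sf[["sfh"]] * 256 * 256,
               (0.43 * 512) * (0.43 * 448))
  expect_error(scale_factors(c(256, 256), c(0, 256), c(1, 1)), "positive")
})

test_that("count_pixels is the triple sum of the binary mask", {
  expect_equal(count_pixels(lesion_mask(array(0L, c(2, 4, 4)))), 0)
  expect_equal(count_pixels(lesion_mask(array(1L, c(2, 4, 4)))), 32)
  m <- random_mask(c(5L, 12L, 9L), p = 0.4, seed = 42)
  brute <- 0L
  for (n in 1:5) for (h in 1:12) for (w in 1:9) brute <- brute + m$voxels[n, h, w]
  expect_equal(count_pixels(m), brute)
})

test_that("estimate_volume composes scale factors, spacing and count", {
  st <- random_study(c(5L, 20L, 20L), pixel_spacing_mm = c(1, 1),
                     slice_thickness_mm = 3)
  empty <- lesion_mask(array(0L, c(5L, 20L, 20L)))
  expect_equal(estimate_volume(empty, st)$volume_cc, 0)

  set.seed(8)
  v <- array(0L, c(5L, 20L, 20L)); v[sample(length(v), 1000)] <- 1L
  ev <- estimate_volume(lesion_mask(v), st)
  expect_equal(ev$pixel_count, 1000)
  expect_equal(ev$per_pixel_volume_mm3, 3)
  expect_equal(ev$volume_cc, 3.0)
})

test_that("native-geometry estimates equal the brute-force oracle to the last bit", {
  for (s in 1:20) {
    st <- random_study(c(4L, 18L, 22L), pixel_spacing_mm = runif(2, 0.4, 1.2),
                       slice_thickness_mm = runif(1, 1, 5), seed = s)
    m <- random_mask(c(4L, 18L, 22L), p = 0.3, seed = s + 100)
    expect_identical(estimate_volume(m, st)$volume_cc, true_volume_cc(m, st))
  }
})

test_that("volume is monotone in foreground and linear in through-plane spacing", {
  st <- random_study(c(3L, 16L, 16L), pixel_spacing_mm = c(0.8, 0.9),
                     slice_thickness_mm = 2.5)
  m <- random_mask(c(3L, 16L, 16L), p = 0.2, seed = 3)
  v1 <- estimate_volume(m, st)$volume_cc
  grown <- m$voxels; grown[which(grown == 0L)[1:10]] <- 1L
  expect_gt(estimate_volume(lesion_mask(grown), st)$volume_cc, v1)

  st2 <- st; st2$slice_thickness_mm <- 5
  expect_equal(estimate_volume(m, st2)$volume_cc, v1 * 2)
})

test_that("resized-mask volumetry recovers the native volume for large spheres", {
  ph <- sphere_phantom(matrix_size = 128, n_slices = 16, radius_mm = 10,
                       pixel_spacing_mm = c(1, 1), slice_thickness_mm = 3)
  truth <- true_volume_cc(ph$mask, ph$study)
  small <- mask_to_model_geometry(ph$mask, c(64L, 64L))
  est <- estimate_volume(small, ph$study)$volume_cc
  expect_lt(abs(est - truth) / truth, 0.05)
})

test_that("volume reports tabulate one row per patient", {
  st <- random_study(c(3L, 16L, 16L), id = "a")
  st2 <- random_study(c(3L, 16L, 16L), id = "b", seed = 2)
  vr <- volume_report(list(random_mask(c(3L, 16L, 16L)), random_mask(c(3L, 16L, 16L), seed = 2)),
                      list(st, st2))
  expect_equal(vr$patient_id, c("a", "b"))
  expect_true(all(c("pixel_count", "sfw_mm", "sfh_mm", "si_mm", "volume_cc") %in% names(vr)))
})
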