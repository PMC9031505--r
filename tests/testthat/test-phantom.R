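test_that("phantom specs are validated field by field", {
  expect_error(phantom_spec(matrix_size = 8), "matrix_size")
  expect_error(phantom_spec(n_slices = 2), "n_slices")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(background_intensity = 500, lesion_intensity = 400),
               "lesion_intensity")
  expect_error(lesion_blob(c(0, 0, 0), c(1, -1, 1)), "radii_mm")
})

test_that("a phantom with no lesions has an empty mask", {
  spec <- phantom_spec(matrix_size = 32, n_slices = 6, lesions = list(),
                       noise_sigma = 0)
  ph <- generate_phantom(spec)
  expect_equal(sum(ph$mask$voxels), 0)
  expect_equal(dim(ph$study$voxels), c(6L, 32L, 32L))
})

test_that("mask voxel centres satisfy the ellipsoid inequality and carry the lesion intensity", {
  ph <- sphere_phantom(matrix_size = 48, n_slices = 16, radius_mm = 9,
                       pixel_spacing_mm = c(1.5, 1.5), slice_thickness_mm = 3)
  spec_centre <- c(16 * 3, 48 * 1.5, 48 * 1.5) / 2
  idx <- which(ph$mask$voxels == 1, arr.ind = TRUE)
  z <- (idx[, 1] - 0.5) * 3; y <- (idx[, 2] - 0.5) * 1.5; x <- (idx[, 3] - 0.5) * 1.5
  r2 <- ((z - spec_centre[1])^2 + (y - spec_centre[2])^2 + (x - spec_centre[3])^2) / 9^2
  expect_true(all(r2 <= 1 + 1e-12))
  # noise-free: lesion voxels carry exactly the lesion intensity
  expect_true(all(ph$study$voxels[ph$mask$voxels == 1] == 1200))
})

test_that("rasterized sphere volume approaches the analytic ellipsoid volume", {
  ph <- sphere_phantom(matrix_size = 64, n_slices = 20, radius_mm = 6,
                       pixel_spacing_mm = c(1, 1), slice_thickness_mm = 3)
  analytic_voxels <- (4 / 3) * pi * 6^3 / 3   # volume / voxel volume
  count <- sum(ph$mask$voxels)
  expect_lt(abs(count - analytic_voxels) / analytic_voxels, 0.10)
})

test_that("generation is bit-identical under a fixed spec and seed", {
  spec <- phantom_spec(matrix_size = 32, n_slices = 8,
                       lesions = list(lesion_blob(c(12, 16, 16), c(5, 6, 7),
                                                  perturb = 0.1)),
                       noise_sigma = 15, seed = 99)
  a <- generate_phantom(spec); b <- generate_phantom(spec)
  expect_identical(a$study$voxels, b$study$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
})

test_that("true_volume_cc multiplies count by voxel volume and respects slice order", {
  m <- random_mask(c(4L, 20L, 20L), p = 0.3, seed = 5)
  st <- random_study(c(4L, 20L, 20L), pixel_spacing_mm = c(1, 1),
                     slice_thickness_mm = 3)
  expect_equal(true_volume_cc(m, st), sum(m$voxels) * 3 / 1000)
  # per-slice summation order agrees exactly
  per_slice <- sum(vapply(1:4, function(k) sum(m$voxels[k, , ]) * 3 / 1000, numeric(1)))
  expect_equal(true_volume_cc(m, st), per_slice)
  # reordering slices of mask and study together leaves the volume unchanged
  ord <- c(3, 1, 4, 2)
  m2 <- lesion_mask(m$voxels[ord, , ])
  st2 <- st; st2$voxels <- st$voxels[ord, , ]
  expect_identical(true_volume_cc(m2, st2), true_volume_cc(m, st))
  expect_error(true_volume_cc(random_mask(c(3L, 20L, 20L)), st), "shapes differ")
})

test_that("make_cohort is deterministic and spans small and large lesion regimes", {
  r <- list(matrix_size = 64L, n_slices = c(10L, 14L), radius_mm = c(2, 20))
  a <- make_cohort(6, r, seed = 7)
  b <- make_cohort(6, r, seed = 7)
  expect_identical(cohort_manifest(a), cohort_manifest(b))
  expect_length(make_cohort(1, r, seed = 1), 1L)

  vols <- cohort_manifest(make_cohort(40, r, seed = 3))$true_volume_cc
  expect_true(any(vols < 1))
  expect_true(any(vols > 10))
  expect_error(make_cohort(3, list(radius_mm = c(5, 2))), "radius_mm")
})
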