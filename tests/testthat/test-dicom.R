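test_that("a phantom study round-trips through a DICOM series losslessly", {
  ph <- sphere_phantom(matrix_size = 32, n_slices = 6, radius_mm = 8,
                       noise_sigma = 12, seed = 4)
  dir <- withr::local_tempdir()
  write_dicom_series(ph$study, dir)
  back <- read_dicom_series(dir)
  expect_identical(back$voxels, ph$study$voxels)
  expect_equal(back$pixel_spacing_mm, ph$study$pixel_spacing_mm)
  expect_equal(back$slice_thickness_mm, ph$study$slice_thickness_mm)
  expect_null(back$spacing_between_slices_mm)
  expect_equal(back$patient_id, ph$study$patient_id)
})

test_that("slice order is recovered from spatial positions, not filenames", {
  ph <- sphere_phantom(matrix_size = 32, n_slices = 5, radius_mm = 7, seed = 2)
  dir <- withr::local_tempdir()
  write_dicom_series(ph$study, dir)
  files <- list.files(dir, full.names = TRUE)
  # shuffle names so lexicographic order disagrees with acquisition order
  tmp <- paste0(files, ".tmp")
  file.rename(files, tmp)
  set.seed(1)
  file.rename(sample(tmp), files)
  expect_identical(read_dicom_series(dir)$voxels, ph$study$voxels)
})

test_that("through-plane spacing prefers SpacingBetweenSlices over SliceThickness", {
  st <- random_study(c(3L, 16L, 16L), slice_thickness_mm = 3)
  expect_equal(resolve_through_plane_spacing(st), 3)
  st$spacing_between_slices_mm <- 3.5
  expect_equal(resolve_through_plane_spacing(st), 3.5)
  st2 <- st; st2$slice_thickness_mm <- NULL; st2$spacing_between_slices_mm <- NULL
  expect_error(resolve_through_plane_spacing(st2), "neither")

  # both header configurations resolve to the same spacing after a
  # DICOM roundtrip, and estimate_volume agrees between them
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  a <- random_study(c(3L, 16L, 16L), slice_thickness_mm = 3.0, id = "a")
  b <- random_study(c(3L, 16L, 16L), slice_thickness_mm = 3.0,
                    spacing_between_slices_mm = 3.0, id = "b")
  write_dicom_series(a, dir1); write_dicom_series(b, dir2)
  ra <- read_dicom_series(dir1); rb <- read_dicom_series(dir2)
  expect_equal(resolve_through_plane_spacing(ra), 3.0)
  expect_equal(resolve_through_plane_spacing(rb), 3.0)
  m <- random_mask(c(3L, 16L, 16L), p = 0.3, seed = 9)
  expect_equal(estimate_volume(m, ra)$volume_cc, estimate_volume(m, rb)$volume_cc)
})

test_that("mask series round-trip preserves the pixel count and binarity", {
  m <- random_mask(c(4L, 24L, 24L), p = 0.25, seed = 31)
  dir <- withr::local_tempdir()
  write_mask(m, dir)
  back <- read_mask(dir)
  expect_identical(back$voxels, m$voxels)
  expect_equal(count_pixels(back), count_pixels(m))

  zero <- lesion_mask(array(0L, c(3, 16, 16)))
  dir2 <- withr::local_tempdir()
  write_mask(zero, dir2)
  expect_equal(sum(read_mask(dir2)$voxels), 0)

  bad <- lesion_mask(array(1L, c(3, 16, 16)))
  bad$voxels[1] <- 2L
  expect_error(write_mask(bad, withr::local_tempdir()), "binary")
})

test_that("files from different series are rejected", {
  a <- random_study(c(3L, 16L, 16L), id = "a")
  b <- random_study(c(3L, 16L, 16L), id = "b", seed = 2)
  dir <- withr::local_tempdir()
  write_dicom_series(a, dir)
  dirb <- withr::local_tempdir()
  write_dicom_series(b, dirb)
  file.copy(list.files(dirb, full.names = TRUE)[1],
            file.path(dir, "stray.dcm"))
  expect_error(read_dicom_series(dir), "mixed series")
})

test_that("the series is readable by an independent DICOM implementation", {
  py <- Sys.which("python")
  ph <- sphere_phantom(matrix_size = 24, n_slices = 4, radius_mm = 6, seed = 6)
  dir <- withr::local_tempdir()
  write_dicom_series(ph$study, dir)
  script <- paste(
    "import sys, pydicom, numpy as np, glob",
    "files = sorted(glob.glob(sys.argv[1] + '/*.dcm'))",
    "dss = [pydicom.dcmread(f) for f in files]",
    "dss.sort(key=lambda d: float(d.ImagePositionPatient[2]))",
    "vol = np.stack([d.pixel_array for d in dss])",
    "print(int(vol.sum()), float(dss[0].PixelSpacing[0]), float(dss[0].SliceThickness))",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2(py, c(sf, dir), stdout = TRUE)
  vals <- strsplit(out[1], " ")[[1]]
  expect_equal(as.numeric(vals[1]), sum(ph$study$voxels))
  expect_equal(as.numeric(vals[2]), ph$study$pixel_spacing_mm[1])
  expect_equal(as.numeric(vals[3]), ph$study$slice_thickness_mm)
})
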