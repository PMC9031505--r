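test_that("slice triplets replicate edges and cover every slice", {
  ph <- sphere_phantom(matrix_size = 16, n_slices = 5, radius_mm = 5, seed = 8)
  tr <- make_triplets(ph$study)
  expect_length(tr, 5L)
  # middle triplet channels are the adjacent slices, bit-exactly
  expect_identical(tr[[3]]$channels[1, , ], ph$study$voxels[2, , ])
  expect_identical(tr[[3]]$channels[2, , ], ph$study$voxels[3, , ])
  expect_identical(tr[[3]]$channels[3, , ], ph$study$voxels[4, , ])
  # edges replicate the boundary slice
  expect_identical(tr[[1]]$channels[1, , ], tr[[1]]$channels[2, , ])
  expect_identical(tr[[5]]$channels[3, , ], tr[[5]]$channels[2, , ])

  one <- dwi_study(ph$study$voxels[1, , , drop = FALSE], c(1, 1), 3)
  t1 <- make_triplets(one)
  expect_length(t1, 1L)
  expect_identical(t1[[1]]$channels[1, , ], t1[[1]]$channels[3, , ])
})

test_that("patient splits honour the 8:1:1 ratio and are seed-stable", {
  ids <- sprintf("p%02d", 1:10)
  s <- split_cohort(ids, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(lengths(s), c(train = 8L, validation = 1L, test = 1L))
  expect_identical(s, split_cohort(ids, c(0.8, 0.1, 0.1), seed = 4))
  expect_false(identical(s, split_cohort(ids, c(0.8, 0.1, 0.1), seed = 5)))
  expect_setequal(unlist(s), ids)
  s40 <- split_cohort(sprintf("p%02d", 1:40), seed = 1)
  expect_equal(lengths(s40), c(train = 32L, validation = 4L, test = 4L))
  expect_error(split_cohort(c("a", "b"), c(0.8, 0.1, 0.1)), "too small")
  expect_error(train_config(split_ratios = c(0.5, 0.5, 0.1)), "sum to 1")
  expect_error(train_config(threshold = 1.2), "threshold")
})

test_that("a tiny indirect model reduces validation loss on an easy cohort", {
  cohort <- make_cohort(5, list(matrix_size = 32L, n_slices = 6L,
                                radius_mm = c(6, 12), noise_sigma = 10),
                        seed = 14)
  mc <- unet_config(dimensionality = 2, depth = 2, base_channels = 4, seed = 14)
  tc <- train_config(epochs = 3, batch_size = 8, target_size = c(32L, 32L),
                     split_ratios = c(0.6, 0.2, 0.2), seed = 14)
  fit <- train_model(mc, tc, cohort)
  expect_equal(nrow(fit$history), 3L)
  expect_lt(fit$history$val_loss[3], fit$history$val_loss[1])
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  # broom-style accessors
  expect_identical(tidy(fit), fit$history)
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
  # identical seeds give identical training trajectories
  fit2 <- train_model(mc, tc, cohort)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$split, fit2$split)
})

test_that("prediction restacks slices and respects the threshold", {
  cohort <- make_cohort(5, list(matrix_size = 32L, n_slices = 6L,
                                radius_mm = c(6, 12), noise_sigma = 10),
                        seed = 14)
  mc <- unet_config(dimensionality = 2, depth = 2, base_channels = 4, seed = 14)
  tc <- train_config(epochs = 2, batch_size = 8, target_size = c(32L, 32L),
                     split_ratios = c(0.6, 0.2, 0.2), seed = 14)
  fit <- train_model(mc, tc, cohort)
  st <- cohort[[1]]$study
  pred <- predict_indirect(fit, st)
  expect_equal(dim(pred$voxels), dim(st$voxels))
  expect_true(all(pred$voxels %in% c(0L, 1L)))
  # a model forced to emit ~0 probability yields an empty mask
  zfit <- fit
  zfit$model$params[["out.W"]][] <- 0
  zfit$model$params[["out.b"]][] <- -50
  expect_equal(sum(predict_indirect(zfit, st)$voxels), 0)
  expect_error(predict_direct(fit, st), "3D")
})

test_that("checkpoints round-trip the whole fit", {
  cohort <- make_cohort(5, list(matrix_size = 32L, n_slices = 6L,
                                radius_mm = c(6, 12)), seed = 3)
  mc <- unet_config(dimensionality = 2, depth = 2, base_channels = 4, seed = 3)
  tc <- train_config(epochs = 1, batch_size = 8, target_size = c(32L, 32L),
                     split_ratios = c(0.6, 0.2, 0.2), seed = 3)
  fit <- train_model(mc, tc, cohort)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(back$model$params, fit$model$params)
  expect_identical(back$history, fit$history)
  st <- cohort[[1]]$study
  expect_identical(predict_indirect(back, st)$voxels,
                   predict_indirect(fit, st)$voxels)
})
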