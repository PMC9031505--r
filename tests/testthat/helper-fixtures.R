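# Small in-code fixtures shared across tests. Everything is generated at
# test time from fixed seeds; nothing is read from disk.

sphere_phantom <- function(matrix_size = 64L, n_slices = 20L, radius_mm = 6,
                           pixel_spacing_mm = c(1, 1), slice_thickness_mm = 3,
                           noise_sigma = 0, seed = 1L, perturb = 0) {
  ext <- c(n_slices * slice_thickness_mm,
           matrix_size * pixel_spacing_mm[1],
           matrix_size * pixel_spacing_mm[2])
  spec <- phantom_spec(matrix_size = matrix_size, n_slices = n_slices,
                       pixel_spacing_mm = pixel_spacing_mm,
                       slice_thickness_mm = slice_thickness_mm,
                       lesions = list(lesion_blob(ext / 2, rep(radius_mm, 3),
                                                  perturb = perturb)),
                       noise_sigma = noise_sigma, seed = seed)
  generate_phantom(spec)
}

random_mask <- function(dims, p = 0.2, seed = 1L) {
  set.seed(seed)
  lesion_mask(array(rbinom(prod(dims), 1L, p), dim = dims))
}

random_study <- function(dims = c(5L, 16L, 16L), pixel_spacing_mm = c(0.7, 0.9),
                         slice_thickness_mm = 3, spacing_between_slices_mm = NULL,
                         seed = 1L, id = "s1") {
  set.seed(seed)
  dwi_study(array(sample(0:4095, prod(dims), replace = TRUE), dim = dims),
            pixel_spacing_mm = pixel_spacing_mm,
            slice_thickness_mm = slice_thickness_mm,
            spacing_between_slices_mm = spacing_between_slices_mm,
            patient_id = id)
}

# memoized heavy fixture for the phantom-recovery experiments: one 40-
# phantom cohort, one indirect and one direct fit, shared across tests
.acceptance_env <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.acceptance_env$cohort))
    .acceptance_env$cohort <- make_cohort(
      40, list(matrix_size = 64L, n_slices = c(10L, 14L), radius_mm = c(2, 20)),
      seed = 2024L)
  .acceptance_env$cohort
}

acceptance_fit <- function(path = c("indirect", "direct")) {
  path <- match.arg(path)
  key <- paste0("fit_", path)
  if (is.null(.acceptance_env[[key]])) {
    cohort <- acceptance_cohort()
    mc <- unet_config(dimensionality = if (path == "indirect") 2L else 3L,
                      depth = 3L, base_channels = 8L, seed = 2024L)
    # epoch counts chosen for matched wall-clock on one core: a direct-
    # path epoch (patch tiling) costs about twice an indirect epoch
    tc <- train_config(epochs = if (path == "indirect") 8L else 4L,
                       batch_size = 8L,
                       target_size = c(64L, 64L),
                       patch_shape = c(8L, 16L, 16L),
                       seed = 2024L)
    .acceptance_env[[key]] <- train_model(mc, tc, cohort)
  }
  .acceptance_env[[key]]
}

acceptance_test_metrics <- function(path) {
  key <- paste0("metrics_", path)
  if (is.null(.acceptance_env[[key]])) {
    fit <- acceptance_fit(path)
    cohort <- acceptance_cohort()
    ids <- vapply(cohort, function(p) p$study$patient_id, character(1))
    test <- cohort[match(fit$split$test, ids)]
    preds <- lapply(test, function(p)
      if (path == "indirect") predict_indirect(fit, p$study)
      else predict_direct(fit, p$study))
    labels <- lapply(test, `[[`, "mask")
    studies <- lapply(test, `[[`, "study")
    .acceptance_env[[key]] <- evaluate_cohort(preds, labels, studies)
  }
  .acceptance_env[[key]]
}
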