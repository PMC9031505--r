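#' Run configuration for the end-to-end pipeline
#'
#' A single YAML document with per-stage sections drives the pipeline
#' commands; every run writes a frozen copy of its fully resolved
#' configuration into the output directory, and all randomness flows
#' from the global `seed`.
#'
#' @param path YAML file; missing fields fall back to
#'   `default_run_config()`.
#' @return A nested list (`run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(seed = 1L,
       out_dir = "strokevol-run",
       # "n_phantoms", not "n": a bare `n` key is parsed as boolean FALSE
       # by YAML 1.1 readers
       simulate = list(n_phantoms = 12L,
                       ranges = list(matrix_size = 64L, n_slices = c(10L, 14L),
                                     radius_mm = c(3, 16))),
       model = list(depth = 3L, base_channels = 8L),
       train = list(epochs = 6L, batch_size = 8L, learning_rate = 1e-3,
                    target_size = c(64L, 64L),
                    patch_shape = c(8L, 32L, 32L)),
       predict = list(subset = "test"))
}

freeze_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
}

require_artifact <- function(path, stage, hint) {
  if (!file.exists(path))
    stop(stage, " needs the missing artifact '", path, "' - run ", hint,
         " first", call. = FALSE)
  path
}

#' Pipeline stages
#'
#' The five commands mirror the method's end-to-end flow — synthesize (or
#' supply) a DICOM cohort, train a segmentation model, predict masks,
#' estimate volumes, evaluate — with each stage a pure function of the
#' previous stage's on-disk artifacts.
#'
#' * `run_simulate`: writes one DICOM image series and mask series per
#'   phantom plus `manifest.csv` with the ground-truth volumes.
#' * `run_train`: builds the HDF5 cache from the DICOM cohort, trains the
#'   2D (`path = "indirect"`) or 3D (`path = "direct"`) model, writes a
#'   checkpoint and the per-epoch loss history CSV.
#' * `run_predict`: writes predicted masks (DICOM series at model
#'   geometry) for the chosen subset.
#' * `run_volume`: converts predicted masks to physical volumes
#'   (`volumes-<path>.csv`).
#' * `run_evaluate`: segmentation and volumetry metrics against the
#'   ground-truth masks (per-patient CSV + cohort summary JSON).
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @param path `"indirect"` (2D slice model) or `"direct"` (patch-based
#'   3D model).
#' @return Each stage invisibly returns its main artifact path (or, for
#'   `run_evaluate`, the `metrics_report`).
#' @export
run_simulate <- function(config) {
  out <- config$out_dir
  freeze_config(config, out)
  sim <- config$simulate
  cohort <- make_cohort(sim$n_phantoms, sim$ranges, seed = config$seed)
  root <- file.path(out, "cohort")
  for (p in cohort) {
    pdir <- file.path(root, p$study$patient_id)
    write_dicom_series(p$study, file.path(pdir, "image"))
    write_mask(p$mask, file.path(pdir, "mask"), study = p$study)
  }
  manifest <- cohort_manifest(cohort)
  write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  invisible(file.path(out, "manifest.csv"))
}

load_cohort_from_disk <- function(out) {
  root <- require_artifact(file.path(out, "cohort"), "this stage", "`run_simulate`")
  ids <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  lapply(ids, function(id) {
    study <- read_dicom_series(file.path(root, id, "image"))
    mask <- read_mask(file.path(root, id, "mask"))
    list(study = study, mask = mask)
  })
}

cache_path <- function(out) file.path(out, "cache.h5")

#' @rdname run_simulate
#' @export
run_train <- function(config, path = c("indirect", "direct")) {
  path <- match.arg(path)
  out <- config$out_dir
  freeze_config(config, out)
  cp <- cache_path(out)
  if (!file.exists(cp)) {
    cohort <- load_cohort_from_disk(out)
    cache_hdf5(lapply(cohort, `[[`, "study"), lapply(cohort, `[[`, "mask"), cp)
  }
  cached <- load_hdf5(cp)
  cohort <- Map(function(s, m) list(study = s, mask = m), cached$studies, cached$masks)
  tc <- do.call(train_config, c(config$train, list(seed = config$seed)))
  mc <- unet_config(dimensionality = if (path == "indirect") 2L else 3L,
                    depth = config$model$depth,
                    base_channels = config$model$base_channels,
                    seed = config$seed)
  fit <- train_model(mc, tc, cohort)
  ckpt <- file.path(out, sprintf("checkpoint-%s.rds", path))
  save_checkpoint(fit, ckpt)
  write.csv(fit$history, file.path(out, sprintf("history-%s.csv", path)),
            row.names = FALSE)
  invisible(ckpt)
}

predict_subset_ids <- function(fit, config, all_ids) {
  subset <- config$predict$subset %||% "test"
  if (subset == "all") all_ids else fit$split$test
}

#' @rdname run_simulate
#' @export
run_predict <- function(config, path = c("indirect", "direct")) {
  path <- match.arg(path)
  out <- config$out_dir
  ckpt <- require_artifact(file.path(out, sprintf("checkpoint-%s.rds", path)),
                           "run_predict", "`run_train`")
  fit <- load_checkpoint(ckpt)
  cached <- load_hdf5(require_artifact(cache_path(out), "run_predict", "`run_train`"))
  ids <- vapply(cached$studies, function(s) s$patient_id, character(1))
  want <- predict_subset_ids(fit, config, ids)
  pdir <- file.path(out, sprintf("predictions-%s", path))
  for (id in want) {
    study <- cached$studies[[match(id, ids)]]
    mask <- if (path == "indirect") predict_indirect(fit, study)
            else predict_direct(fit, study)
    write_mask(mask, file.path(pdir, id), study = study)
  }
  invisible(pdir)
}

#' @rdname run_simulate
#' @export
run_volume <- function(config, path = c("indirect", "direct")) {
  path <- match.arg(path)
  out <- config$out_dir
  pdir <- require_artifact(file.path(out, sprintf("predictions-%s", path)),
                           "run_volume", "`run_predict`")
  cached <- load_hdf5(require_artifact(cache_path(out), "run_volume", "`run_train`"))
  ids <- vapply(cached$studies, function(s) s$patient_id, character(1))
  want <- sort(list.dirs(pdir, recursive = FALSE, full.names = FALSE))
  rows <- lapply(want, function(id) {
    study <- cached$studies[[match(id, ids)]]
    mask <- read_mask(file.path(pdir, id))
    if (!all(dim(mask$voxels)[2:3] == study$original_size))
      mask$alignment <- "resized"
    tidy(estimate_volume(mask, study))
  })
  vr <- do.call(rbind, rows)
  vf <- file.path(out, sprintf("volumes-%s.csv", path))
  write.csv(vr, vf, row.names = FALSE)
  invisible(vf)
}

#' @rdname run_simulate
#' @export
run_evaluate <- function(config, path = c("indirect", "direct")) {
  path <- match.arg(path)
  out <- config$out_dir
  pdir <- require_artifact(file.path(out, sprintf("predictions-%s", path)),
                           "run_evaluate", "`run_predict`")
  cached <- load_hdf5(require_artifact(cache_path(out), "run_evaluate", "`run_train`"))
  ids <- vapply(cached$studies, function(s) s$patient_id, character(1))
  want <- sort(list.dirs(pdir, recursive = FALSE, full.names = FALSE))
  preds <- list(); labels <- list(); studies <- list()
  for (id in want) {
    study <- cached$studies[[match(id, ids)]]
    pred <- read_mask(file.path(pdir, id))
    geom <- dim(pred$voxels)[2:3]
    pred$alignment <- if (all(geom == study$original_size)) "native" else "resized"
    label <- cached$masks[[match(id, ids)]]
    if (!all(dim(label$voxels)[2:3] == geom))
      label <- mask_to_model_geometry(label, geom)
    preds[[id]] <- pred; labels[[id]] <- label; studies[[id]] <- study
  }
  rep <- evaluate_cohort(preds, labels, studies)
  write.csv(rep$per_patient, file.path(out, sprintf("evaluation-%s.csv", path)),
            row.names = FALSE)
  jsonlite::write_json(as.list(rep$summary),
                       file.path(out, sprintf("evaluation-%s.json", path)),
                       auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
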