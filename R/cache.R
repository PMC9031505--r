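#' Cache studies and masks to HDF5
#'
#' Loading and parsing many DICOM files is slow, so the training pipeline
#' reads from an HDF5 cache: one group per patient with datasets `image`
#' (slices x H x W), `mask`, `spacing` (row, column, slice thickness,
#' spacing between slices; the last is NaN when the header lacked it) and
#' `original_size`. Loading the cache reconstructs exactly the
#' DICOM-derived representation and never consults the DICOM files.
#' Patients are written in sorted id order so identical inputs produce
#' identical cache content.
#'
#' @param studies list of [dwi_study()] objects.
#' @param masks list of matching [lesion_mask()] objects.
#' @param path HDF5 file to create (overwritten if present).
#' @return `path`, invisibly.
#' @export
cache_hdf5 <- function(studies, masks, path) {
  stopifnot(length(studies) == length(masks))
  ids <- vapply(studies, function(s) s$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort", call. = FALSE)
  ord <- order(ids)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (i in ord) {
    s <- studies[[i]]; m <- masks[[i]]
    stopifnot_aligned(m, s)
    g <- paste0("/", s$patient_id)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(s$voxels, path, paste0(g, "/image"))
    rhdf5::h5write(m$voxels, path, paste0(g, "/mask"))
    rhdf5::h5write(c(s$pixel_spacing_mm,
                     s$slice_thickness_mm %||% NaN,
                     s$spacing_between_slices_mm %||% NaN),
                   path, paste0(g, "/spacing"))
    rhdf5::h5write(as.integer(s$original_size), path, paste0(g, "/original_size"))
  }
  invisible(path)
}

#' @rdname cache_hdf5
#' @return For `load_hdf5`: a list with `studies` and `masks`, in sorted
#'   patient-id order.
#' @export
load_hdf5 <- function(path) {
  if (!file.exists(path)) stop("cache file not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- tryCatch(rhdf5::h5ls(path, recursive = FALSE),
                 error = function(e) stop("corrupt HDF5 cache: ", path, call. = FALSE))
  ids <- sort(ls$name[ls$otype == "H5I_GROUP"])
  if (length(ids) == 0) stop("HDF5 cache has no patient groups: ", path, call. = FALSE)
  studies <- vector("list", length(ids)); masks <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- paste0("/", ids[i])
    img <- rhdf5::h5read(path, paste0(g, "/image"))
    msk <- rhdf5::h5read(path, paste0(g, "/mask"))
    sp <- as.numeric(rhdf5::h5read(path, paste0(g, "/spacing")))
    osz <- as.integer(rhdf5::h5read(path, paste0(g, "/original_size")))
    if (length(sp) != 4L) stop("corrupt HDF5 cache (spacing): ", path, call. = FALSE)
    studies[[i]] <- dwi_study(img, pixel_spacing_mm = sp[1:2],
                              slice_thickness_mm = if (is.nan(sp[3])) NULL else sp[3],
                              spacing_between_slices_mm = if (is.nan(sp[4])) NULL else sp[4],
                              original_size = osz, patient_id = ids[i])
    masks[[i]] <- lesion_mask(array(as.integer(msk), dim = dim(msk)))
  }
  list(studies = studies, masks = masks)
}
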