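#' Resize slices to the model resolution
#'
#' Training and inference run at a fixed in-plane resolution (256 x 256
#' by default) to bound compute. Image slices are resized with bilinear
#' interpolation; mask slices with nearest-neighbour so they stay binary.
#' Spacing metadata is never changed by resizing: the volumetry absorbs
#' the resize through scale factors computed from `original_size`.
#'
#' @param slice 2D numeric matrix.
#' @param target integer (height, width) of the output.
#' @return Resized matrix (binary integer matrix for `resize_mask`).
#' @export
resize_for_model <- function(slice, target = c(256L, 256L)) {
  if (any(target <= 0)) stop("resize target must be positive", call. = FALSE)
  if (all(dim(slice) == target)) return(slice)
  EBImage::resize(slice, w = target[1], h = target[2], filter = "bilinear")
}

#' @rdname resize_for_model
#' @export
resize_mask <- function(slice, target = c(256L, 256L)) {
  if (any(target <= 0)) stop("resize target must be positive", call. = FALSE)
  if (!all(slice %in% c(0, 1))) stop("mask slice must be binary", call. = FALSE)
  if (all(dim(slice) == target)) {
    out <- slice
  } else {
    out <- EBImage::resize(slice, w = target[1], h = target[2], filter = "none")
  }
  storage.mode(out) <- "integer"
  out
}

#' Bring a study or mask volume to model geometry
#'
#' Applies the per-slice resize to every slice of a volume.
#' `study_to_model_geometry` keeps spacing metadata and `original_size`
#' untouched (they parameterize the volumetry scale factors);
#' `mask_to_model_geometry` returns a mask tagged with `"resized"`
#' alignment.
#'
#' @param study a [dwi_study()]; `mask` a [lesion_mask()].
#' @param target integer (height, width) model resolution.
#' @return A resized [dwi_study()] / [lesion_mask()].
#' @export
study_to_model_geometry <- function(study, target = c(256L, 256L)) {
  d <- dim(study$voxels)
  if (all(d[2:3] == target)) return(study)
  out <- array(0, dim = c(d[1], target))
  for (k in seq_len(d[1])) out[k, , ] <- resize_for_model(study$voxels[k, , ], target)
  study$voxels <- out
  study
}

#' @param mask a [lesion_mask()].
#' @rdname study_to_model_geometry
#' @export
mask_to_model_geometry <- function(mask, target = c(256L, 256L)) {
  d <- dim(mask$voxels)
  out <- array(0L, dim = c(d[1], target))
  for (k in seq_len(d[1])) out[k, , ] <- resize_mask(mask$voxels[k, , ], target)
  lesion_mask(out, alignment = if (all(d[2:3] == target)) mask$alignment else "resized")
}
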