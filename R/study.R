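#' DWI study and lesion mask containers
#'
#' A `dwi_study` wraps a 3D intensity array (slices x rows x columns) with
#' the spacing metadata needed for physical volumetry: in-plane pixel
#' spacing (row, column) in mm, slice thickness in mm, optionally the
#' centre-to-centre spacing between slices in mm, and the original in-plane
#' matrix size. `original_size` is carried separately from the stored array
#' shape so that volumes can still be computed after the in-plane resize to
#' the model resolution.
#'
#' @param voxels numeric 3D array, dimensions (slices, rows, columns).
#' @param pixel_spacing_mm positive numeric pair (row spacing, column
#'   spacing) in mm.
#' @param slice_thickness_mm positive scalar, mm.
#' @param spacing_between_slices_mm positive scalar in mm, or `NULL` when
#'   the header does not carry it.
#' @param original_size integer pair (height, width) of the acquisition
#'   matrix; defaults to the in-plane dimensions of `voxels`.
#' @param patient_id opaque identifier string.
#' @return An object of class `dwi_study`.
#' @export
dwi_study <- function(voxels, pixel_spacing_mm, slice_thickness_mm,
                      spacing_between_slices_mm = NULL,
                      original_size = NULL, patient_id = "anon") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (slices x rows x columns)", call. = FALSE)
  d <- dim(voxels)
  if (d[1] < 1L || d[2] < 16L || d[3] < 16L)
    stop("`voxels` needs >= 1 slice and in-plane size >= 16", call. = FALSE)
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop("`pixel_spacing_mm` must be a positive (row, column) pair", call. = FALSE)
  if (!is.null(slice_thickness_mm) &&
      (length(slice_thickness_mm) != 1L || slice_thickness_mm <= 0))
    stop("`slice_thickness_mm` must be a positive scalar", call. = FALSE)
  if (!is.null(spacing_between_slices_mm) &&
      (length(spacing_between_slices_mm) != 1L || spacing_between_slices_mm <= 0))
    stop("`spacing_between_slices_mm` must be a positive scalar or NULL",
         call. = FALSE)
  if (is.null(slice_thickness_mm) && is.null(spacing_between_slices_mm))
    stop("at least one of `slice_thickness_mm` and `spacing_between_slices_mm` is required",
         call. = FALSE)
  if (is.null(original_size)) original_size <- d[2:3]
  original_size <- as.integer(original_size)
  if (length(original_size) != 2L || any(original_size <= 0))
    stop("`original_size` must be a positive (height, width) pair", call. = FALSE)
  structure(
    list(voxels = voxels,
         pixel_spacing_mm = pixel_spacing_mm,
         slice_thickness_mm = if (is.null(slice_thickness_mm)) NULL else as.numeric(slice_thickness_mm),
         spacing_between_slices_mm = if (is.null(spacing_between_slices_mm)) NULL else as.numeric(spacing_between_slices_mm),
         original_size = original_size,
         patient_id = as.character(patient_id)),
    class = "dwi_study")
}

#' @export
print.dwi_study <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dwi_study> %s: %d slices x %d x %d\n", x$patient_id, d[1], d[2], d[3]))
  cat(sprintf("  pixel spacing %.4g x %.4g mm, slice thickness %s mm, between-slices %s mm\n",
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              if (is.null(x$slice_thickness_mm)) "-" else format(x$slice_thickness_mm),
              if (is.null(x$spacing_between_slices_mm)) "-" else format(x$spacing_between_slices_mm)))
  cat(sprintf("  original matrix %d x %d\n", x$original_size[1], x$original_size[2]))
  invisible(x)
}

#' @param alignment `"native"` if the mask indexes the acquisition geometry,
#'   `"resized"` if it indexes the model-resolution geometry.
#' @rdname dwi_study
#' @export
lesion_mask <- function(voxels, alignment = c("native", "resized")) {
  alignment <- match.arg(alignment)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask `voxels` must be a 3D array", call. = FALSE)
  v <- as.vector(voxels)
  if (!all(v %in% c(0, 1)))
    stop("mask voxels must be binary (0/1)", call. = FALSE)
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, alignment = alignment), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<lesion_mask> %d x %d x %d (%s geometry), %d foreground voxels\n",
              d[1], d[2], d[3], x$alignment, sum(x$voxels)))
  invisible(x)
}

stopifnot_aligned <- function(mask, study) {
  if (!inherits(mask, "lesion_mask")) stop("`mask` must be a lesion_mask", call. = FALSE)
  if (!inherits(study, "dwi_study")) stop("`study` must be a dwi_study", call. = FALSE)
  if (mask$alignment == "native" && !identical(dim(mask$voxels), dim(study$voxels)))
    stop("mask and study shapes differ: mask ",
         paste(dim(mask$voxels), collapse = "x"), " vs study ",
         paste(dim(study$voxels), collapse = "x"), call. = FALSE)
  if (mask$alignment == "resized" && dim(mask$voxels)[1] != dim(study$voxels)[1])
    stop("resized mask must keep the study's slice count", call. = FALSE)
  invisible(TRUE)
}
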