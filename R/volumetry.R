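#' Physical scale factors of a resized mask pixel
#'
#' After the in-plane resize to the model resolution, one mask pixel
#' covers `original/resized` acquisition pixels along each axis. The scale
#' factors are the physical side lengths of one resized-mask pixel:
#' `sfw = column_spacing * (W_original / W_resized)` and
#' `sfh = row_spacing * (H_original / H_resized)`, in mm. Multiplied by
#' the through-plane spacing they give the volume of one counted pixel,
#' so total lesion volume is recovered from a pixel count at model
#' resolution without upsampling the mask.
#'
#' @param original_size integer (height, width) of the acquisition matrix.
#' @param resized_size integer (height, width) of the mask grid.
#' @param pixel_spacing_mm positive (row, column) spacing in mm.
#' @return Named numeric vector `c(sfw = ..., sfh = ...)` in mm.
#' @export
scale_factors <- function(original_size, resized_size, pixel_spacing_mm) {
  original_size <- as.numeric(original_size); resized_size <- as.numeric(resized_size)
  if (any(resized_size <= 0)) stop("resized dimensions must be positive", call. = FALSE)
  if (any(original_size <= 0)) stop("original dimensions must be positive", call. = FALSE)
  if (any(pixel_spacing_mm <= 0)) stop("pixel spacing must be positive", call. = FALSE)
  c(sfw = pixel_spacing_mm[2] * (original_size[2] / resized_size[2]),
    sfh = pixel_spacing_mm[1] * (original_size[1] / resized_size[1]))
}

#' Count predicted lesion pixels
#'
#' The total pixel count is the triple sum of the binary mask over width,
#' height and slices.
#'
#' @param mask a [lesion_mask()] (any geometry).
#' @return Nonnegative integer count.
#' @export
count_pixels <- function(mask) {
  if (!inherits(mask, "lesion_mask")) stop("`mask` must be a lesion_mask", call. = FALSE)
  v <- mask$voxels
  if (!all(v == 0L | v == 1L)) stop("mask must be binary", call. = FALSE)
  sum(v)
}

#' Estimate lesion volume from a segmentation mask
#'
#' Composes the volumetry chain: per-pixel volume
#' `V = sfw * sfh * si` (mm3), with `sfw`, `sfh` from [scale_factors()]
#' and `si` the through-plane spacing from
#' [resolve_through_plane_spacing()]; pixel count `P` from
#' [count_pixels()]; volume `= P * V / 1000` cc. A native-geometry mask
#' has unit scale ratios, so the estimate then equals [true_volume_cc()]
#' exactly.
#'
#' @param mask a [lesion_mask()], native or resized geometry; its slice
#'   count must equal the study's.
#' @param study the [dwi_study()] supplying `original_size` and spacings.
#' @return A `volume_estimate` object: list with `pixel_count`,
#'   `per_pixel_volume_mm3`, `volume_cc`, `scale_factors_mm`,
#'   `through_plane_mm`, `patient_id`.
#' @export
estimate_volume <- function(mask, study) {
  stopifnot_aligned(mask, study)
  si <- resolve_through_plane_spacing(study)
  resized <- if (mask$alignment == "resized") dim(mask$voxels)[2:3] else study$original_size
  sf <- scale_factors(study$original_size, resized, study$pixel_spacing_mm)
  P <- count_pixels(mask)
  V <- sf[["sfw"]] * sf[["sfh"]] * si
  structure(list(pixel_count = P,
                 per_pixel_volume_mm3 = V,
                 volume_cc = P * V / 1000,
                 scale_factors_mm = sf,
                 through_plane_mm = si,
                 patient_id = study$patient_id),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("<volume_estimate> %s: P = %d pixels, V = %.5g mm3/pixel, volume = %.4g cc\n",
              x$patient_id, x$pixel_count, x$per_pixel_volume_mm3, x$volume_cc))
  invisible(x)
}

#' @export
tidy.volume_estimate <- function(x, ...) {
  tibble::tibble(patient_id = x$patient_id, pixel_count = x$pixel_count,
                 sfw_mm = x$scale_factors_mm[["sfw"]],
                 sfh_mm = x$scale_factors_mm[["sfh"]],
                 si_mm = x$through_plane_mm,
                 volume_cc = x$volume_cc)
}

#' Volume report for a set of predictions
#'
#' @param masks list of [lesion_mask()] predictions.
#' @param studies list of matching [dwi_study()] objects.
#' @return A tibble with one row per patient: `patient_id`,
#'   `pixel_count`, `sfw_mm`, `sfh_mm`, `si_mm`, `volume_cc`.
#' @export
volume_report <- function(masks, studies) {
  stopifnot(length(masks) == length(studies))
  rows <- Map(function(m, s) tidy(estimate_volume(m, s)), masks, studies)
  do.call(rbind, rows)
}
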