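# Minimal single-frame DICOM I/O, Explicit VR Little Endian only.
# Covers exactly what spacing-aware volumetry needs: unsigned 16-bit
# monochrome pixel data plus the geometry tags (PixelSpacing 0028,0030;
# SliceThickness 0018,0050; SpacingBetweenSlices 0018,0088;
# ImagePositionPatient 0020,0032). Multi-frame/enhanced objects,
# compressed transfer syntaxes and sequences are out of scope.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_MR <- "1.2.840.10008.5.1.4.1.1.4"
UID_ROOT <- "1.2.826.0.1.3680043.10.5001"

dcm_pad <- function(raw, pad = as.raw(0L)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

dcm_uint <- function(x, size) {
  # little-endian unsigned integer of 2 or 4 bytes
  x <- as.numeric(x)
  b <- raw(size)
  for (i in seq_len(size)) { b[i] <- as.raw(x %% 256); x <- x %/% 256 }
  b
}

dcm_element <- function(group, element, vr, value_raw) {
  value_raw <- dcm_pad(value_raw, pad = if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" "))
  head <- c(dcm_uint(group, 2L), dcm_uint(element, 2L), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), dcm_uint(length(value_raw), 4L), value_raw)
  } else {
    if (length(value_raw) > 65534) stop("value too long for short-form VR", call. = FALSE)
    c(head, dcm_uint(length(value_raw), 2L), value_raw)
  }
}

dcm_str_element <- function(group, element, vr, text) {
  dcm_element(group, element, vr, charToRaw(text))
}

dcm_ds <- function(x) paste(vapply(x, function(v) format(v, digits = 15, scientific = FALSE),
                                   character(1)), collapse = "\\")

dcm_pixels_raw <- function(mat) {
  v <- as.integer(round(as.vector(t(mat))))   # DICOM stores row-major
  if (any(v < 0 | v > 65535)) stop("pixel values out of 16-bit unsigned range", call. = FALSE)
  b <- raw(2L * length(v))
  b[seq(1L, length(b), 2L)] <- as.raw(v %% 256L)
  b[seq(2L, length(b), 2L)] <- as.raw(v %/% 256L)
  b
}

write_dicom_slice <- function(mat, path, pixel_spacing_mm, slice_thickness_mm,
                              spacing_between_slices_mm, instance_number,
                              position_mm, patient_id, series_uid, study_uid) {
  sop_uid <- paste(UID_ROOT, study_uid_num(study_uid), instance_number,
                   sep = ".")
  ds <- list(
    dcm_str_element(0x0008, 0x0016, "UI", SOP_CLASS_MR),
    dcm_str_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_str_element(0x0008, 0x0060, "CS", "MR"),
    dcm_str_element(0x0010, 0x0020, "LO", patient_id),
    dcm_str_element(0x0018, 0x0050, "DS", dcm_ds(slice_thickness_mm)))
  if (!is.null(spacing_between_slices_mm))
    ds <- c(ds, list(dcm_str_element(0x0018, 0x0088, "DS", dcm_ds(spacing_between_slices_mm))))
  ds <- c(ds, list(
    dcm_str_element(0x0020, 0x000D, "UI", study_uid),
    dcm_str_element(0x0020, 0x000E, "UI", series_uid),
    dcm_str_element(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_str_element(0x0020, 0x0032, "DS", dcm_ds(position_mm)),
    dcm_str_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", dcm_uint(1L, 2L)),
    dcm_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", dcm_uint(nrow(mat), 2L)),
    dcm_element(0x0028, 0x0011, "US", dcm_uint(ncol(mat), 2L)),
    dcm_str_element(0x0028, 0x0030, "DS", dcm_ds(pixel_spacing_mm)),
    dcm_element(0x0028, 0x0100, "US", dcm_uint(16L, 2L)),
    dcm_element(0x0028, 0x0101, "US", dcm_uint(16L, 2L)),
    dcm_element(0x0028, 0x0102, "US", dcm_uint(15L, 2L)),
    dcm_element(0x0028, 0x0103, "US", dcm_uint(0L, 2L)),
    dcm_element(0x7FE0, 0x0010, "OW", dcm_pixels_raw(mat))))
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str_element(0x0002, 0x0002, "UI", SOP_CLASS_MR),
    dcm_str_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_str_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
    dcm_str_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1")))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint(length(meta_body), 4L)), meta_body)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, do.call(c, ds)), con)
  invisible(path)
}

study_uid_num <- function(uid) {
  # short stable numeric token from a UID string, for building child UIDs
  sum(utf8ToInt(uid) * seq_along(utf8ToInt(uid))) %% 100000L
}

# --- reading -----------------------------------------------------------

read_uint <- function(b, off, size) {
  sum(as.numeric(b[off + seq_len(size) - 1L]) * 256^(seq_len(size) - 1L))
}

parse_dicom_file <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  if (length(b) < 140L || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  elems <- list()
  transfer <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(b)) {
    group <- read_uint(b, pos, 2L); element <- read_uint(b, pos + 2L, 2L)
    vr <- rawToChar(b[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit VR?) encoding in ", path, call. = FALSE)
    if (vr %in% long_vrs) {
      len <- read_uint(b, pos + 8L, 4L); body <- pos + 12L
    } else {
      len <- read_uint(b, pos + 6L, 2L); body <- pos + 8L
    }
    if (vr == "SQ") stop("sequences are not supported", call. = FALSE)
    key <- sprintf("%04X,%04X", group, element)
    val_raw <- if (len > 0) b[body + seq_len(len) - 1L] else raw(0)
    elems[[key]] <- list(vr = vr, raw = val_raw)
    if (key == "0002,0010") transfer <- trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
    if (!is.null(transfer) && group > 2L && transfer != TRANSFER_SYNTAX_EXPLICIT_LE)
      stop("unsupported transfer syntax: ", transfer, call. = FALSE)
    pos <- body + len
  }
  elems
}

dcm_get_str <- function(elems, key, required = FALSE) {
  e <- elems[[key]]
  if (is.null(e)) {
    if (required) stop("missing DICOM tag (", key, ")", call. = FALSE)
    return(NULL)
  }
  trimws(rawToChar(e$raw[e$raw != as.raw(0)]))
}

dcm_get_num <- function(elems, key, required = FALSE) {
  s <- dcm_get_str(elems, key, required)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_get_uint <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) stop("missing DICOM tag (", key, ")", call. = FALSE)
  read_uint(e$raw, 1L, length(e$raw))
}

dcm_get_pixels <- function(elems, rows, cols) {
  e <- elems[["7FE0,0010"]]
  if (is.null(e)) stop("missing PixelData (7FE0,0010)", call. = FALSE)
  v <- as.numeric(e$raw[seq(1L, 2L * rows * cols, 2L)]) +
    256 * as.numeric(e$raw[seq(2L, 2L * rows * cols, 2L)])
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}

#' Read a single-frame DICOM series as a DWI study
#'
#' Reads every `.dcm` file under `path`, verifies they belong to one
#' series, sorts slices by the projection of ImagePositionPatient on the
#' slice normal (falling back to InstanceNumber when positions are
#' absent), and assembles the intensity volume with its spacing metadata.
#' Stored values are returned as-is (no windowing or rescaling).
#'
#' @param path directory containing one series of single-frame `.dcm`
#'   files.
#' @return A [dwi_study()].
#' @export
read_dicom_series <- function(path) {
  files <- sort(list.files(path, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0) stop("no .dcm files under ", path, call. = FALSE)
  parsed <- lapply(files, parse_dicom_file)
  series <- vapply(parsed, function(e) dcm_get_str(e, "0020,000E", required = TRUE), character(1))
  if (length(unique(series)) != 1L)
    stop("mixed series in ", path, " (", length(unique(series)), " SeriesInstanceUIDs)", call. = FALSE)
  ps <- dcm_get_num(parsed[[1]], "0028,0030")
  if (is.null(ps)) stop("missing PixelSpacing (0028,0030): volumetry impossible", call. = FALSE)
  thick <- dcm_get_num(parsed[[1]], "0018,0050")
  between <- dcm_get_num(parsed[[1]], "0018,0088")
  if (is.null(thick) && is.null(between))
    stop("missing both SliceThickness (0018,0050) and SpacingBetweenSlices (0018,0088)",
         call. = FALSE)
  # sort by position along the slice normal, fallback instance number
  ori <- dcm_get_num(parsed[[1]], "0020,0037")
  pos_key <- vapply(parsed, function(e) {
    ipp <- dcm_get_num(e, "0020,0032")
    if (is.null(ipp) || is.null(ori)) return(NA_real_)
    normal <- c(ori[2] * ori[6] - ori[3] * ori[5],
                ori[3] * ori[4] - ori[1] * ori[6],
                ori[1] * ori[5] - ori[2] * ori[4])
    sum(ipp * normal)
  }, numeric(1))
  if (anyNA(pos_key))
    pos_key <- vapply(parsed, function(e) dcm_get_num(e, "0020,0013", required = TRUE), numeric(1))
  parsed <- parsed[order(pos_key)]
  rows <- dcm_get_uint(parsed[[1]], "0028,0010")
  cols <- dcm_get_uint(parsed[[1]], "0028,0011")
  vol <- array(0, dim = c(length(parsed), rows, cols))
  for (k in seq_along(parsed)) vol[k, , ] <- dcm_get_pixels(parsed[[k]], rows, cols)
  dwi_study(vol,
            pixel_spacing_mm = ps,
            slice_thickness_mm = thick,
            spacing_between_slices_mm = between,
            patient_id = dcm_get_str(parsed[[1]], "0010,0020") %||% "anon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve the through-plane spacing of a study
#'
#' The per-slice physical depth used by volumetry: SpacingBetweenSlices
#' when the header carries it (the centre-to-centre distance, correct when
#' inter-slice gaps exist), otherwise SliceThickness.
#'
#' @param study a [dwi_study()].
#' @return Positive spacing in mm.
#' @export
resolve_through_plane_spacing <- function(study) {
  if (!is.null(study$spacing_between_slices_mm)) return(study$spacing_between_slices_mm)
  if (!is.null(study$slice_thickness_mm)) return(study$slice_thickness_mm)
  stop("study has neither SpacingBetweenSlices nor SliceThickness", call. = FALSE)
}

#' Write a DWI study as a single-frame DICOM series
#'
#' One Explicit-VR-Little-Endian file per slice, with PixelSpacing,
#' SliceThickness, SpacingBetweenSlices (when present) and
#' ImagePositionPatient populated so the series round-trips through
#' [read_dicom_series()] losslessly. Voxel values must lie on the
#' 16-bit unsigned integer grid.
#'
#' @param study a [dwi_study()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dicom_series <- function(study, path) {
  if (!inherits(study, "dwi_study")) stop("`study` must be a dwi_study", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(study$voxels)
  si <- resolve_through_plane_spacing(study)
  series_uid <- paste(UID_ROOT, "2", abs(study_uid_num(study$patient_id)) + 1L, sep = ".")
  study_uid <- paste(UID_ROOT, "3", abs(study_uid_num(study$patient_id)) + 1L, sep = ".")
  for (k in seq_len(d[1])) {
    write_dicom_slice(study$voxels[k, , ],
                      file.path(path, sprintf("slice-%04d.dcm", k)),
                      pixel_spacing_mm = study$pixel_spacing_mm,
                      slice_thickness_mm = study$slice_thickness_mm %||% si,
                      spacing_between_slices_mm = study$spacing_between_slices_mm,
                      instance_number = k,
                      position_mm = c(0, 0, (k - 1) * si),
                      patient_id = study$patient_id,
                      series_uid = series_uid, study_uid = study_uid)
  }
  invisible(path)
}

#' Write and read lesion masks
#'
#' Masks are stored either as a parallel single-frame DICOM series
#' (pixel values 0/1, same geometry tags as the study) or as a single
#' volumetric NIfTI file. [read_mask()] dispatches on the path: a
#' directory is read as a DICOM series, a `.nii`/`.nii.gz` file through
#' RNifti.
#'
#' @param mask a binary [lesion_mask()].
#' @param path output directory (DICOM) or `.nii`/`.nii.gz` filename.
#' @param study optional [dwi_study()] supplying geometry for the DICOM
#'   series; unit spacings are written otherwise.
#' @param format `"dicom"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, study = NULL, format = c("dicom", "nifti")) {
  format <- match.arg(format)
  if (!inherits(mask, "lesion_mask")) stop("`mask` must be a lesion_mask", call. = FALSE)
  if (!all(mask$voxels %in% c(0L, 1L))) stop("mask must be binary", call. = FALSE)
  if (format == "nifti") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required for NIfTI mask output", call. = FALSE)
    arr <- aperm(mask$voxels, c(3, 2, 1))   # NIfTI is (x, y, z)
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    return(invisible(path))
  }
  vox <- mask$voxels
  ms <- if (is.null(study)) {
    dwi_study(array(as.numeric(vox), dim = dim(vox)),
              pixel_spacing_mm = c(1, 1), slice_thickness_mm = 1,
              patient_id = "mask")
  } else {
    dwi_study(array(as.numeric(vox), dim = dim(vox)),
              pixel_spacing_mm = study$pixel_spacing_mm,
              slice_thickness_mm = study$slice_thickness_mm,
              spacing_between_slices_mm = study$spacing_between_slices_mm,
              patient_id = paste0(study$patient_id, "-mask"))
  }
  write_dicom_series(ms, path)
}

#' @param alignment geometry tag to attach to the mask read back.
#' @rdname write_mask
#' @export
read_mask <- function(path, alignment = "native") {
  if (dir.exists(path)) {
    st <- read_dicom_series(path)
    vox <- st$voxels
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required for NIfTI mask input", call. = FALSE)
    arr <- as.array(RNifti::readNifti(path))
    vox <- aperm(arr, c(3, 2, 1))
  } else stop("cannot read mask from ", path, call. = FALSE)
  if (!all(vox %in% c(0, 1))) stop("mask file is not binary", call. = FALSE)
  lesion_mask(array(as.integer(vox), dim = dim(vox)), alignment = alignment)
}
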