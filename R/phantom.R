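#' Specify a synthetic DWI phantom
#'
#' A phantom is an ellipsoidal "brain" of uniform background intensity
#' containing one or more hyperintense ellipsoidal lesion blobs, with
#' additive Gaussian noise. Default geometry follows a typical stroke DWI
#' acquisition: a 256 x 256 matrix over a 220 mm field of view (0.859 mm
#' in-plane pixel spacing), 24 slices of 3 mm thickness. Lesions are
#' hyperintense relative to the background, as infarcts are on b=1000
#' s/mm2 DWI. Intensities are quantized to the 16-bit unsigned integer
#' grid so that DICOM pixel storage round-trips losslessly.
#'
#' @param matrix_size square in-plane matrix dimension (pixels), >= 16.
#' @param n_slices number of axial slices, >= 3.
#' @param pixel_spacing_mm positive (row, column) spacing in mm.
#' @param slice_thickness_mm positive slice thickness in mm.
#' @param spacing_between_slices_mm optional centre-to-centre slice spacing
#'   in mm (`NULL` to omit, as many headers do).
#' @param lesions list of [lesion_blob()] descriptions (may be empty).
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise (0 disables noise).
#' @param background_intensity,lesion_intensity brain and lesion
#'   intensities; the lesion must be brighter.
#' @param seed integer seed driving the noise.
#' @return A `phantom_spec` object.
#' @seealso [generate_phantom()], [make_cohort()]
#' @export
phantom_spec <- function(matrix_size = 256L, n_slices = 24L,
                         pixel_spacing_mm = c(220 / 256, 220 / 256),
                         slice_thickness_mm = 3,
                         spacing_between_slices_mm = NULL,
                         lesions = list(),
                         noise_sigma = 20,
                         background_intensity = 400,
                         lesion_intensity = 1200,
                         seed = 1L) {
  if (matrix_size < 16L) stop("`matrix_size` must be >= 16", call. = FALSE)
  if (n_slices < 3L) stop("`n_slices` must be >= 3", call. = FALSE)
  if (any(pixel_spacing_mm <= 0)) stop("`pixel_spacing_mm` must be positive", call. = FALSE)
  if (slice_thickness_mm <= 0) stop("`slice_thickness_mm` must be positive", call. = FALSE)
  if (!is.null(spacing_between_slices_mm) && spacing_between_slices_mm <= 0)
    stop("`spacing_between_slices_mm` must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative", call. = FALSE)
  if (lesion_intensity <= background_intensity)
    stop("`lesion_intensity` must exceed `background_intensity` (DWI hyperintensity)",
         call. = FALSE)
  for (b in lesions)
    if (!inherits(b, "lesion_blob")) stop("`lesions` must be a list of lesion_blob objects", call. = FALSE)
  structure(
    list(matrix_size = as.integer(matrix_size), n_slices = as.integer(n_slices),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         spacing_between_slices_mm = if (is.null(spacing_between_slices_mm)) NULL else as.numeric(spacing_between_slices_mm),
         lesions = lesions, noise_sigma = as.numeric(noise_sigma),
         background_intensity = as.numeric(background_intensity),
         lesion_intensity = as.numeric(lesion_intensity),
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Describe one ellipsoidal lesion blob
#'
#' Blobs are ellipsoids in physical (mm) coordinates, optionally with a
#' low-frequency radial perturbation that roughens the boundary while
#' keeping the volume close to the analytic ellipsoid volume.
#'
#' @param center_mm physical centre (z, y, x) in mm; z is the through-plane
#'   axis, y the row axis, x the column axis, all measured from the volume
#'   corner.
#' @param radii_mm positive semi-axes (z, y, x) in mm.
#' @param perturb nonnegative amplitude of the radial perturbation
#'   (fractional; 0 = exact ellipsoid).
#' @param phase two phase angles (radians) fixing the perturbation pattern.
#' @export
lesion_blob <- function(center_mm, radii_mm, perturb = 0, phase = c(0, 0)) {
  center_mm <- as.numeric(center_mm); radii_mm <- as.numeric(radii_mm)
  if (length(center_mm) != 3L) stop("`center_mm` must have 3 components", call. = FALSE)
  if (length(radii_mm) != 3L || any(radii_mm <= 0))
    stop("`radii_mm` must be 3 positive components", call. = FALSE)
  if (perturb < 0) stop("`perturb` must be nonnegative", call. = FALSE)
  structure(list(center_mm = center_mm, radii_mm = radii_mm,
                 perturb = as.numeric(perturb), phase = as.numeric(phase)),
            class = "lesion_blob")
}

# Physical coordinates of voxel centres along each axis (1-based grid).
voxel_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

phantom_through_spacing <- function(spec) {
  if (!is.null(spec$spacing_between_slices_mm)) spec$spacing_between_slices_mm
  else spec$slice_thickness_mm
}

# Rasterize one blob on the voxel-centre grid: a voxel belongs to the blob
# iff its centre satisfies the (perturbed) ellipsoid inequality.
rasterize_blob <- function(blob, zc, yc, xc) {
  nz <- length(zc); ny <- length(yc); nx <- length(xc)
  dz <- (zc - blob$center_mm[1]) / blob$radii_mm[1]
  dy <- (yc - blob$center_mm[2]) / blob$radii_mm[2]
  dx <- (xc - blob$center_mm[3]) / blob$radii_mm[3]
  Z <- array(dz, dim = c(nz, ny, nx))
  Y <- array(rep(dy, each = nz), dim = c(nz, ny, nx))
  X <- array(rep(dx, each = nz * ny), dim = c(nz, ny, nx))
  r2 <- Z^2 + Y^2 + X^2
  if (blob$perturb > 0) {
    theta <- atan2(Y, X)
    phi <- atan2(sqrt(X^2 + Y^2), Z)
    f <- 1 + blob$perturb * sin(3 * theta + blob$phase[1]) * cos(2 * phi + blob$phase[2])
    r2 <= f^2
  } else {
    r2 <= 1
  }
}

#' Generate a synthetic DWI study with a known lesion mask
#'
#' Rasterizes the phantom described by `spec` on its voxel grid: voxels
#' whose centre falls inside any lesion blob take `lesion_intensity`, the
#' rest of the brain ellipsoid takes `background_intensity`, and i.i.d.
#' Gaussian noise of sd `noise_sigma` is added before quantization to the
#' integer grid (clamped to the 16-bit unsigned range). The mask marks
#' exactly the lesion-rasterized voxels. The same spec (including its seed)
#' always yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with components `study` (a [dwi_study()]) and `mask`
#'   (a [lesion_mask()] in native geometry).
#' @examples
#' spec <- phantom_spec(matrix_size = 64, n_slices = 12,
#'                      pixel_spacing_mm = c(1, 1),
#'                      lesions = list(lesion_blob(c(18, 32, 32), c(6, 6, 6))),
#'                      noise_sigma = 0)
#' ph <- generate_phantom(spec)
#' true_volume_cc(ph$mask, ph$study)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec", call. = FALSE)
  nz <- spec$n_slices; ny <- spec$matrix_size; nx <- spec$matrix_size
  sz <- phantom_through_spacing(spec)
  zc <- voxel_centers(nz, sz)
  yc <- voxel_centers(ny, spec$pixel_spacing_mm[1])
  xc <- voxel_centers(nx, spec$pixel_spacing_mm[2])
  # brain: centred ellipsoid filling most of the field of view
  brain <- rasterize_blob(
    lesion_blob(center_mm = c(mean(range(zc)), mean(range(yc)), mean(range(xc))),
                radii_mm = c(0.95 * nz * sz / 2, 0.85 * ny * spec$pixel_spacing_mm[1] / 2,
                             0.85 * nx * spec$pixel_spacing_mm[2] / 2)),
    zc, yc, xc)
  mask <- array(FALSE, dim = c(nz, ny, nx))
  for (b in spec$lesions) mask <- mask | rasterize_blob(b, zc, yc, xc)
  vox <- array(0, dim = c(nz, ny, nx))
  vox[brain] <- spec$background_intensity
  vox[mask] <- spec$lesion_intensity
  if (spec$noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    vox <- vox + rnorm(length(vox), sd = spec$noise_sigma)
  }
  vox <- round(vox)
  vox[vox < 0] <- 0
  vox[vox > 65535] <- 65535
  study <- dwi_study(vox,
                     pixel_spacing_mm = spec$pixel_spacing_mm,
                     slice_thickness_mm = spec$slice_thickness_mm,
                     spacing_between_slices_mm = spec$spacing_between_slices_mm,
                     patient_id = sprintf("phantom-%08d", spec$seed %% 1e8))
  list(study = study, mask = lesion_mask(array(as.integer(mask), dim = dim(mask))))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Ground-truth lesion volume of a mask at native geometry
#'
#' Brute-force volumetry: the voxel count times the physical voxel volume
#' (row spacing x column spacing x through-plane spacing), reported in cc.
#' This is the oracle against which the resize-aware pixel-counting
#' volumetry is validated.
#'
#' @param mask a [lesion_mask()] aligned to `study` at native geometry.
#' @param study the [dwi_study()] carrying the spacing metadata.
#' @return Volume in cc (1 cc = 1000 mm3).
#' @export
true_volume_cc <- function(mask, study) {
  stopifnot_aligned(mask, study)
  if (mask$alignment != "native")
    stop("true_volume_cc needs a native-geometry mask", call. = FALSE)
  vv <- study$pixel_spacing_mm[1] * study$pixel_spacing_mm[2] *
    resolve_through_plane_spacing(study)
  sum(mask$voxels) * vv / 1000
}

#' Generate a reproducible cohort of phantoms
#'
#' Samples `n` phantom specifications from parameter ranges and generates
#' them. Ranges are `(min, max)` pairs (scalars are fixed values). Lesion
#' count, per-lesion radius and boundary perturbation are drawn uniformly;
#' lesion centres are placed inside the central portion of the brain so
#' blobs stay within the volume. With a radius range spanning small and
#' large lesions the cohort covers both sub-cc and multi-cc regimes.
#'
#' @param n number of phantoms (>= 1).
#' @param ranges named list overriding any of: `matrix_size`, `n_slices`,
#'   `pixel_spacing_mm`, `slice_thickness_mm`, `noise_sigma`,
#'   `background_intensity`, `lesion_intensity`, `n_lesions`, `radius_mm`,
#'   `perturb`. `n_slices`, `n_lesions`, `radius_mm` and `perturb` may be
#'   `(min, max)` ranges.
#' @param seed integer seed; the whole cohort is a pure function of
#'   `(n, ranges, seed)`.
#' @return A list of `n` elements, each a `list(study, mask, spec)`.
#' @export
make_cohort <- function(n, ranges = list(), seed = 1L) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  defaults <- list(matrix_size = 64L, n_slices = c(10L, 14L),
                   pixel_spacing_mm = c(1, 1), slice_thickness_mm = 3,
                   noise_sigma = 20, background_intensity = 400,
                   lesion_intensity = 1200,
                   n_lesions = c(1L, 3L), radius_mm = c(2, 20),
                   perturb = c(0, 0.15))
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown)) stop("unknown range field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  r <- utils::modifyList(defaults, ranges)
  for (f in c("n_slices", "n_lesions", "radius_mm", "perturb"))
    if (length(r[[f]]) == 1L) r[[f]] <- rep(r[[f]], 2L)
  if (r$radius_mm[1] <= 0 || r$radius_mm[2] < r$radius_mm[1])
    stop("invalid `radius_mm` range", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # sample() treats a length-1 vector as 1:x; draw from the range safely
  draw_int <- function(lo, hi) if (lo == hi) as.integer(lo) else sample(seq(lo, hi), 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ms <- r$matrix_size
    nsl <- draw_int(r$n_slices[1], r$n_slices[2])
    sz <- r$slice_thickness_mm
    ext <- c(nsl * sz, ms * r$pixel_spacing_mm[1], ms * r$pixel_spacing_mm[2])
    nles <- draw_int(r$n_lesions[1], r$n_lesions[2])
    blobs <- vector("list", nles)
    for (j in seq_len(nles)) {
      # log-uniform: lesion volumes scale with radius^3, so a uniform draw
      # would almost never produce the small sub-cc regime
      rad <- exp(runif(1, log(r$radius_mm[1]), log(r$radius_mm[2])))
      radii <- rad * runif(3, 0.8, 1.2)
      radii <- pmin(radii, 0.45 * ext)   # keep the blob inside the volume
      ctr <- ext / 2 + runif(3, -0.25, 0.25) * ext
      ctr <- pmin(pmax(ctr, radii + 0.05 * ext), ext - radii - 0.05 * ext)
      ctr <- pmin(pmax(ctr, 0), ext)
      blobs[[j]] <- lesion_blob(ctr, radii, perturb = runif(1, r$perturb[1], r$perturb[2]),
                                phase = runif(2, 0, 2 * pi))
    }
    spec <- phantom_spec(matrix_size = ms, n_slices = nsl,
                         pixel_spacing_mm = r$pixel_spacing_mm,
                         slice_thickness_mm = sz,
                         lesions = blobs, noise_sigma = r$noise_sigma,
                         background_intensity = r$background_intensity,
                         lesion_intensity = r$lesion_intensity,
                         seed = sample.int(.Machine$integer.max, 1L))
    ph <- generate_phantom(spec)
    ph$study$patient_id <- sprintf("phantom-%03d", i)
    out[[i]] <- list(study = ph$study, mask = ph$mask, spec = spec)
  }
  out
}

#' Tabulate a cohort's ground truth
#'
#' @param cohort result of [make_cohort()].
#' @return A tibble with one row per phantom: `patient_id`, `n_slices`,
#'   `matrix_size`, `voxel_count`, `true_volume_cc`.
#' @export
cohort_manifest <- function(cohort) {
  tibble::tibble(
    patient_id = vapply(cohort, function(p) p$study$patient_id, character(1)),
    n_slices = vapply(cohort, function(p) dim(p$study$voxels)[1], integer(1)),
    matrix_size = vapply(cohort, function(p) dim(p$study$voxels)[2], integer(1)),
    voxel_count = vapply(cohort, function(p) sum(p$mask$voxels), integer(1)),
    true_volume_cc = vapply(cohort, function(p) true_volume_cc(p$mask, p$study), numeric(1)))
}
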