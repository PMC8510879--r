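# Volume I/O and slice handling: body-weight SUV computation, resampling onto
# the CT grid, slice-label derivation, NIfTI read/write, slice extraction.
#
# Axis convention (package-wide): volumes are arrays (row, col, slice) with
# 0-based voxel indices mapping to physical coordinates index * spacing
# (voxel centers at integer grid coordinates, origin at voxel 0).

#' Compute body-weight SUV from an activity map
#'
#' Standardized uptake value with decay correction of the injected dose to
#' scan time: `SUV = activity * body weight (g) / (dose * 2^(-t / T_half))`.
#' With tissue density taken as 1 g/ml the result is unitless but reported in
#' g/ml by convention.
#'
#' @param activity activity concentration grid (Bq/ml), any shape.
#' @param body_weight_kg patient body weight in kg.
#' @param injected_dose_bq injected dose in Bq at injection time.
#' @param elapsed_time_s time from injection to scan, seconds.
#' @param half_life_s tracer half-life in seconds (default: 18F, 109.77 min).
#' @return SUV grid (g/ml), same shape as `activity`.
#' @export
compute_suv <- function(activity, body_weight_kg, injected_dose_bq,
                        elapsed_time_s = 0, half_life_s = 6586.2) {
  if (body_weight_kg <= 0 || injected_dose_bq <= 0 || half_life_s <= 0)
    stop("compute_suv: weight, dose and half-life must be positive", call. = FALSE)
  if (elapsed_time_s < 0)
    stop("compute_suv: elapsed_time_s must be nonnegative", call. = FALSE)
  decayed_dose <- injected_dose_bq * 2^(-elapsed_time_s / half_life_s)
  activity * (body_weight_kg * 1000) / decayed_dose
}

#' Resample a volume onto a target grid by trilinear interpolation
#'
#' Both grids share the physical position of voxel (0, 0, 0); target voxel
#' `i` samples the source at physical coordinate `i * target_spacing`.
#' Interpolation is clamp-to-edge, so output values never leave the source
#' value range. The identity mapping (same spacing, same shape) reproduces
#' the input exactly.
#'
#' @param volume 3D array `(row, col, slice)`.
#' @param spacing source voxel spacing (mm), length 3.
#' @param target_spacing target voxel spacing (mm), length 3.
#' @param target_shape target grid shape, length 3.
#' @return 3D array of dim `target_shape`.
#' @export
resample_to_grid <- function(volume, spacing, target_spacing, target_shape) {
  if (length(dim(volume)) != 3L || any(dim(volume) < 1L) || length(volume) == 0L)
    stop("resample_to_grid: volume must be a non-degenerate 3D array", call. = FALSE)
  if (any(spacing <= 0) || any(target_spacing <= 0) || any(target_shape < 1))
    stop("resample_to_grid: spacings and shapes must be positive", call. = FALSE)
  cpp_resample_trilinear(volume, as.numeric(spacing), as.numeric(target_spacing),
                         as.integer(target_shape))
}

#' Derive per-slice binary labels from a segmentation mask
#'
#' The weak supervision signal: slice `i` is labelled 1 iff any voxel of
#' slice `i` (third array margin) is positive.
#'
#' @param mask 3D binary array `(row, col, slice)`.
#' @return integer vector of 0/1 labels, one per slice.
#' @export
derive_slice_labels <- function(mask) {
  if (!all(mask %in% c(0, 1)))
    stop("derive_slice_labels: mask must be binary", call. = FALSE)
  as.integer(apply(mask, 3L, function(s) any(s == 1)))
}

#' Write / read a volume sample as NIfTI files
#'
#' One `.nii.gz` file per channel (`<id>_pet.nii.gz`, `<id>_ct.nii.gz`,
#' `<id>_mask.nii.gz`), voxel spacing recorded in the NIfTI header.
#'
#' @param vs a `volume_sample`.
#' @param dir output directory (created if missing).
#' @return `write_volume_sample` returns the paths invisibly;
#'   `read_volume_sample` returns a `volume_sample`.
#' @export
write_volume_sample <- function(vs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(vs$subject_id, "_", c("pet", "ct", "mask"), ".nii.gz"))
  chans <- list(vs$pet_suv, vs$ct_hu, vs$gt_mask)
  for (i in 1:3) {
    img <- RNifti::asNifti(chans[[i]])
    RNifti::pixdim(img) <- vs$voxel_spacing
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' @rdname write_volume_sample
#' @param subject_id subject identifier used in the file names.
#' @export
read_volume_sample <- function(dir, subject_id) {
  rd <- function(ch) {
    img <- RNifti::readNifti(file.path(dir, paste0(subject_id, "_", ch, ".nii.gz")))
    list(arr = array(as.numeric(img), dim(img)), spacing = RNifti::pixdim(img))
  }
  pet <- rd("pet"); ct <- rd("ct"); mk <- rd("mask")
  mask <- array(as.integer(round(mk$arr)), dim(mk$arr))
  structure(list(subject_id = subject_id, pet_suv = pet$arr, ct_hu = ct$arr,
                 gt_mask = mask, voxel_spacing = as.numeric(pet$spacing[1:3]),
                 slice_labels = derive_slice_labels(mask)),
            class = "volume_sample")
}

#' Extract per-slice records from volumes
#'
#' Flattens volumes into the tabular slice representation used by the
#' classifier, the CAM methods and the U-Net: one row per axial slice with
#' matrix list-columns for the PET, CT and (optional) mask channels.
#'
#' @param x a `volume_sample` or a cohort tibble with a `volume` list-column
#'   (and optionally a `split` column, which is carried through).
#' @return tibble with columns `subject_id`, `slice_index`, `label`,
#'   `pet`, `ct`, `mask` (list-columns), `pixel_spacing`, `slice_thickness`
#'   (and `split` if present in the input).
#' @export
extract_slices <- function(x) {
  if (inherits(x, "volume_sample")) {
    d <- dim(x$pet_suv)[3]
    tb <- tibble::tibble(
      subject_id = x$subject_id,
      slice_index = seq_len(d),
      label = x$slice_labels,
      pet = lapply(seq_len(d), function(i) x$pet_suv[, , i]),
      ct = lapply(seq_len(d), function(i) x$ct_hu[, , i]),
      mask = lapply(seq_len(d), function(i) x$gt_mask[, , i]),
      pixel_spacing_x = x$voxel_spacing[1],
      pixel_spacing_y = x$voxel_spacing[2],
      slice_thickness = x$voxel_spacing[3]
    )
    return(tb)
  }
  if (is.data.frame(x) && "volume" %in% names(x)) {
    per <- lapply(seq_len(nrow(x)), function(i) {
      tb <- extract_slices(x$volume[[i]])
      if ("split" %in% names(x)) tb$split <- x$split[i]
      tb
    })
    return(dplyr::bind_rows(per))
  }
  stop("extract_slices: expected a volume_sample or a cohort tibble", call. = FALSE)
}

#' Slice label table
#'
#' The weak-label table (`subject_id`, `slice_index`, `label`) for a cohort
#' or a single volume; write with [readr::write_csv()] for interchange.
#'
#' @param x a `volume_sample` or cohort tibble.
#' @return tibble with one row per slice.
#' @export
slice_label_table <- function(x) {
  dplyr::select(extract_slices(x), dplyr::any_of(c("subject_id", "slice_index", "label")))
}

# stack per-subject slice rows (ordered by slice_index) into a 3D array
stack_slices <- function(mats) {
  array(unlist(mats, use.names = FALSE), dim = c(dim(mats[[1]]), length(mats)))
}
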