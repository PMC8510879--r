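# Adaptive two-threshold segmentation: a CAM threshold t_m carves a
# candidate region out of the activation map; within that region (upscaled
# to image resolution by nearest neighbour) an SUV percentile q_m sets the
# final intensity threshold t_q. Plus the global SUV-percentile baseline.

#' CAM segmentation hyperparameters
#'
#' `t_m` thresholds the normalized activation map in `[0, 1]`; `q_m` is the
#' SUV percentile (percent, `[0, 100]`) taken *inside* the candidate region.
#' Fractional `q_m` in `(0, 1]` is accepted and interpreted as a fraction
#' (0.31 means the 31st percentile), since tuned optima are conventionally
#' quoted either way.
#'
#' @param method CAM method id (one of `cam`, `gradcam`, `gradcam++`,
#'   `scorecam`).
#' @param t_m CAM threshold in `[0, 1]`.
#' @param q_m SUV percentile in `[0, 100]` (or fraction in `(0, 1]`).
#' @return a `cam_params` list.
#' @export
cam_params <- function(method, t_m, q_m) {
  if (q_m > 0 && q_m <= 1) q_m <- 100 * q_m
  if (t_m < 0 || t_m > 1) stop("cam_params: t_m must lie in [0, 1]", call. = FALSE)
  if (q_m < 0 || q_m > 100) stop("cam_params: q_m must lie in [0, 100]", call. = FALSE)
  structure(list(method = method, t_m = t_m, q_m = q_m), class = "cam_params")
}

#' Upscale a binary grid by nearest-neighbour block replication
#'
#' Each input cell becomes an `fr x fc` block; the number of positives
#' multiplies by the (integer) per-axis factors.
#'
#' @param grid binary matrix.
#' @param target_shape (rows, cols), an integer multiple of `dim(grid)`.
#' @return binary matrix of dim `target_shape`.
#' @export
upscale_nearest <- function(grid, target_shape) {
  fr <- target_shape[1] / nrow(grid)
  fc <- target_shape[2] / ncol(grid)
  if (fr != round(fr) || fc != round(fc))
    stop("upscale_nearest: target shape must be an integer multiple of the grid",
         call. = FALSE)
  grid[rep(seq_len(nrow(grid)), each = fr), rep(seq_len(ncol(grid)), each = fc),
       drop = FALSE]
}

new_segmentation_mask <- function(values, method, ...) {
  structure(list(values = values, method = method, ...), class = "segmentation_mask")
}

#' Segment one slice from its activation map (adaptive two-threshold routine)
#'
#' If the classifier calls the slice tumor-free, the mask is empty.
#' Otherwise the candidate region `H' = (M >= t_m)` is upscaled to image
#' resolution by nearest neighbour; `t_q` is the `q_m`-th percentile (linear
#' interpolation between order statistics) of the SUV values inside the
#' candidate region; the final mask keeps candidate positions with
#' `SUV >= t_q`. An empty candidate region yields an empty mask with a
#' warning, not an error.
#'
#' @param slice slice record with a `pet` matrix.
#' @param map an `activation_map` (or plain `[0,1]` matrix).
#' @param params a [cam_params()].
#' @param predicted_tumor classifier decision for this slice.
#' @return a `segmentation_mask` with provenance (`method`, `t_m`, `q_m`,
#'   realized `t_q`).
#' @export
cam_segment <- function(slice, map, params, predicted_tumor) {
  slice <- as_one_slice(slice)
  pet <- slice$pet
  vals <- if (inherits(map, "activation_map")) map$values else map
  if (!predicted_tumor)
    return(new_segmentation_mask(array(0L, dim(pet)), params$method,
                                 t_m = params$t_m, q_m = params$q_m, t_q = NA_real_))
  candidate <- vals >= params$t_m
  if (!any(candidate)) {
    warning("cam_segment: no CAM value reaches t_m; returning empty mask", call. = FALSE)
    return(new_segmentation_mask(array(0L, dim(pet)), params$method,
                                 t_m = params$t_m, q_m = params$q_m, t_q = NA_real_))
  }
  cand_up <- upscale_nearest(candidate, dim(pet))
  suv_in <- pet[cand_up]
  t_q <- unname(stats::quantile(suv_in, params$q_m / 100, type = 7))
  mask <- array(0L, dim(pet))
  mask[cand_up & pet >= t_q] <- 1L
  new_segmentation_mask(mask, params$method, t_m = params$t_m, q_m = params$q_m, t_q = t_q)
}

#' Global SUV-percentile baseline segmentation
#'
#' Empty mask when the classifier calls the slice tumor-free; otherwise all
#' pixels at or above the `q`-th percentile of the whole slice's SUV values.
#'
#' @param slice slice record with a `pet` matrix.
#' @param q SUV percentile in `[0, 100]` (or fraction in `(0, 1]`).
#' @param predicted_tumor classifier decision for this slice.
#' @return a `segmentation_mask`.
#' @export
global_threshold_segment <- function(slice, q, predicted_tumor) {
  slice <- as_one_slice(slice)
  pet <- slice$pet
  if (q > 0 && q <= 1) q <- 100 * q
  if (q < 0 || q > 100) stop("global_threshold_segment: q must lie in [0, 100]", call. = FALSE)
  if (!predicted_tumor)
    return(new_segmentation_mask(array(0L, dim(pet)), "global", q = q, t_q = NA_real_))
  t_q <- unname(stats::quantile(pet, q / 100, type = 7))
  mask <- array(0L, dim(pet))
  mask[pet >= t_q] <- 1L
  new_segmentation_mask(mask, "global", q = q, t_q = t_q)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask %s>  %d positive pixels\n", x$method, sum(x$values)))
  invisible(x)
}

#' Segment all slices of one subject into a 3D mask
#'
#' Runs the per-slice pipeline (classifier gate, then the chosen
#' segmentation method) over a subject's slices and stacks the per-slice
#' masks into the subject volume, ready for 3D evaluation.
#'
#' @param slices slice tibble of one subject, ordered by `slice_index`.
#' @param model `tumor_classifier` used as the gate (and CAM source).
#' @param method `cam`, `gradcam`, `gradcam++`, `scorecam`, `global`, or
#'   `unet`.
#' @param params [cam_params()] for CAM methods; `list(q=)` for `global`;
#'   a trained U-Net for `unet`.
#' @param pred_labels optional precomputed classifier decisions (0/1) per
#'   slice; computed from `model` when missing.
#' @return 3D binary array `(row, col, slice)`.
#' @export
segment_subject <- function(slices, model, method, params, pred_labels = NULL) {
  ord <- order(slices$slice_index)
  slices <- slices[ord, ]
  if (!is.null(pred_labels)) pred_labels <- pred_labels[ord]
  if (method == "unet")
    return(stack_slices(lapply(seq_len(nrow(slices)), function(i)
      predict_unet(params, slices[i, ]))))
  if (is.null(pred_labels))
    pred_labels <- predict(model, slices)$pred_label
  mats <- lapply(seq_len(nrow(slices)), function(i) {
    sl <- slices[i, ]
    pos <- pred_labels[i] == 1L
    if (method == "global") {
      global_threshold_segment(sl, params$q, pos)$values
    } else {
      m <- if (pos) compute_cam(model, sl, method) else
        matrix(0, model$config$feature_shape[1], model$config$feature_shape[2])
      suppressWarnings(cam_segment(sl, m, params, pos)$values)
    }
  })
  stack_slices(mats)
}
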