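# Grid search for the method-specific CAM threshold t_m and SUV percentile
# q_m, maximizing the median per-subject 3D Dice on validation subjects.
# The default grids are 10 linearly spaced t_m in [0.1, 0.9] and 20 linearly
# spaced q_m in [20, 50] (200 candidate pairs). The search is exhaustive;
# ties break to the smallest t_m, then the smallest q_m.

# type-7 quantile on an already-sorted vector, vectorized over p
quantile_sorted <- function(x_sorted, p) {
  n <- length(x_sorted)
  if (n == 1L) return(rep(x_sorted, length(p)))
  h <- (n - 1) * p
  lo <- pmin(floor(h), n - 2)
  x_sorted[lo + 1] + (h - lo) * (x_sorted[lo + 2] - x_sorted[lo + 1])
}

# number of elements of ascending x that are >= t (vectorized over t)
count_ge_sorted <- function(x_sorted, t) {
  length(x_sorted) - findInterval(t, x_sorted, left.open = TRUE)
}

#' Tune (t_m, q_m) for one CAM method by exhaustive grid search
#'
#' Evaluates every candidate pair by running the adaptive-threshold
#' segmentation over the validation subjects and computing each subject's 3D
#' Dice; returns the full grid with the pair maximizing the median Dice.
#' Activation maps are computed once per predicted-positive slice and shared
#' across the grid, which is exact because `t_m` and `q_m` only enter the
#' thresholding.
#'
#' @param model trained `tumor_classifier`.
#' @param method CAM method id (see [compute_cam()]).
#' @param slices validation slice tibble with ground-truth masks.
#' @param tm_grid,qm_grid candidate CAM thresholds and SUV percentiles
#'   (percent).
#' @param pred_labels optional precomputed classifier decisions per slice
#'   (0/1); computed from `model` when missing.
#' @return a `cam_tuning` tibble (`t_m`, `q_m`, `median_dice`) with the best
#'   pair in `attr(, "best")`; see [glance.cam_tuning()].
#' @export
tune_thresholds <- function(model, method, slices,
                            tm_grid = seq(0.1, 0.9, length.out = 10),
                            qm_grid = seq(20, 50, length.out = 20),
                            pred_labels = NULL) {
  method <- match.arg(method, CAM_METHODS)
  if (length(tm_grid) == 0L || length(qm_grid) == 0L)
    stop("tune_thresholds: grids must be nonempty", call. = FALSE)
  grid <- tune_engine(model, method, slices, tm_grid, qm_grid, pred_labels)
  best <- grid[order(-grid$median_dice, grid$t_m, grid$q_m), ][1, ]
  structure(grid, class = c("cam_tuning", class(grid)),
            method = method,
            best = list(t_m = best$t_m, q_m = best$q_m, median_dice = best$median_dice))
}

#' Tune the global SUV-percentile baseline
#'
#' Grid search over the percentile `q` applied to whole slices that the
#' classifier predicts as tumorous, maximizing median per-subject 3D Dice.
#'
#' @param model trained `tumor_classifier`.
#' @param slices validation slice tibble with ground-truth masks.
#' @param q_grid candidate percentiles (percent).
#' @param pred_labels optional precomputed classifier decisions per slice.
#' @return a `cam_tuning` tibble over `q_m` with `attr(, "best")`.
#' @export
tune_global_threshold <- function(model, slices, q_grid = seq(20, 50, length.out = 20),
                                  pred_labels = NULL) {
  grid <- tune_engine(model, "global", slices, tm_grid = 0, qm_grid = q_grid, pred_labels)
  best <- grid[order(-grid$median_dice, grid$q_m), ][1, ]
  structure(grid[, c("q_m", "median_dice")],
            class = c("cam_tuning", class(grid)), method = "global",
            best = list(q_m = best$q_m, median_dice = best$median_dice))
}

tune_engine <- function(model, method, slices, tm_grid, qm_grid, pred_labels = NULL) {
  if (!"mask" %in% names(slices) || any(vapply(slices$mask, is.null, logical(1))))
    stop("tune_thresholds: validation slices need ground-truth masks", call. = FALSE)
  subjects <- unique(slices$subject_id)
  gt_pos <- vapply(slices$mask, function(m) sum(m == 1), numeric(1))
  if (sum(gt_pos) == 0)
    stop("tune_thresholds: no positive validation subject", call. = FALSE)
  pred <- pred_labels %||% predict(model, slices)$pred_label
  n_tm <- length(tm_grid); n_qm <- length(qm_grid); n_s <- length(subjects)
  sub_idx <- match(slices$subject_id, subjects)
  inter <- array(0, c(n_tm, n_qm, n_s))
  npred <- array(0, c(n_tm, n_qm, n_s))
  gt_tot <- tapply(gt_pos, factor(sub_idx, levels = seq_len(n_s)), sum, default = 0)
  p_frac <- qm_grid / 100
  for (i in seq_len(nrow(slices))) {
    if (pred[i] != 1L) next
    pet <- slices$pet[[i]]
    gt <- slices$mask[[i]]
    s <- sub_idx[i]
    if (method == "global") {
      suv_all <- sort(as.numeric(pet))
      suv_gt <- sort(pet[gt == 1])
      tq <- quantile_sorted(suv_all, p_frac)
      npred[1, , s] <- npred[1, , s] + count_ge_sorted(suv_all, tq)
      inter[1, , s] <- inter[1, , s] + count_ge_sorted(suv_gt, tq)
      next
    }
    map <- compute_cam(model, slices[i, ], method)$values
    for (t in seq_len(n_tm)) {
      cand <- map >= tm_grid[t]
      if (!any(cand)) next
      up <- upscale_nearest(cand, dim(pet))
      suv_c <- sort(pet[up])
      suv_cg <- sort(pet[up & gt == 1])
      tq <- quantile_sorted(suv_c, p_frac)
      npred[t, , s] <- npred[t, , s] + count_ge_sorted(suv_c, tq)
      inter[t, , s] <- inter[t, , s] + count_ge_sorted(suv_cg, tq)
    }
  }
  gt_arr <- array(rep(gt_tot, each = n_tm * n_qm), c(n_tm, n_qm, n_s))
  dice <- 2 * inter / (npred + gt_arr)
  dice[(npred + gt_arr) == 0] <- 1 # empty gt and empty prediction
  med <- apply(dice, c(1, 2), stats::median)
  tibble::tibble(t_m = rep(tm_grid, times = n_qm),
                 q_m = rep(qm_grid, each = n_tm),
                 median_dice = as.numeric(med))
}

#' @export
print.cam_tuning <- function(x, ...) {
  b <- attr(x, "best")
  cat(sprintf("<cam_tuning %s>  %d candidates; best:%s q_m = %.3g (median Dice %.3f)\n",
              attr(x, "method"), nrow(x),
              if (!is.null(b$t_m)) sprintf(" t_m = %.3g,", b$t_m) else "",
              b$q_m, b$median_dice))
  NextMethod()
}
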