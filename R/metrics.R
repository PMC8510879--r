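# Per-subject evaluation (3D Dice, MTV, TLG, SUV statistics) and cohort
# statistics (median/IQR; two-way, absolute-agreement intraclass
# correlation between predicted and ground-truth biomarkers).

#' 3D Dice overlap between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks score 1.0 (a correctly
#' predicted absence of tumor), a convention that only arises on synthetic
#' data since clinical subjects in this setting always carry tumor.
#'
#' @param gt,pred binary arrays of identical shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice3d <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred)))
    stop("dice3d: masks must share a shape", call. = FALSE)
  sa <- sum(gt == 1); sb <- sum(pred == 1)
  if (sa + sb == 0) return(1.0)
  2 * sum(gt == 1 & pred == 1) / (sa + sb)
}

#' Metabolic tumor volume (ml)
#'
#' Positive-voxel count times the voxel volume, converted from mm^3 to ml.
#'
#' @param mask binary 3D array.
#' @param spacing voxel spacing (mm), length 3.
#' @return MTV in ml.
#' @export
mtv <- function(mask, spacing) {
  if (any(spacing <= 0)) stop("mtv: spacing must be positive", call. = FALSE)
  sum(mask == 1) * prod(spacing) / 1000
}

#' Total lesion glycolysis (g)
#'
#' Mean SUV over the mask times the MTV; 0 for an empty mask.
#'
#' @param mask binary 3D array.
#' @param suv SUV array of the same shape (g/ml).
#' @param spacing voxel spacing (mm), length 3.
#' @return TLG in g.
#' @export
tlg <- function(mask, suv, spacing) {
  if (!identical(dim(mask), dim(suv)))
    stop("tlg: mask and SUV grids must share a shape", call. = FALSE)
  if (sum(mask == 1) == 0) return(0)
  mean(suv[mask == 1]) * mtv(mask, spacing)
}

#' Intraclass correlation, two-way random, absolute agreement, single measures
#'
#' ICC(2,1) from the two-way mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the F-based
#' 95% confidence interval and p-value of the standard construction
#' (Shrout-Fleiss / McGraw-Wong). Absolute agreement penalizes systematic
#' offsets, unlike Pearson correlation.
#'
#' @param x,y paired measurements (e.g. ground-truth and predicted MTV per
#'   subject), n >= 5.
#' @param conf_level confidence level of the interval.
#' @return an `icc_result`: `icc`, `ci_low`, `ci_high`, `p_value`, mean
#'   squares, `n`, `k`.
#' @export
icc_agreement <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("icc_agreement: x and y must be paired", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x); k <- 2L
  if (n < 5L) stop("icc_agreement: need at least 5 paired values", call. = FALSE)
  m <- cbind(x, y)
  if (stats::var(as.numeric(m)) == 0)
    stop("icc_agreement: zero variance; ICC undefined", call. = FALSE)
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  f_val <- msr / mse
  df2 <- (n - 1) * (k - 1)
  p <- stats::pf(f_val, n - 1, df2, lower.tail = FALSE)
  alpha <- 1 - conf_level
  # McGraw & Wong CI for the agreement/single-measures ICC
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(icc = icc, ci_low = lo, ci_high = hi, p_value = p,
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) agreement = %.3f  95%% CI [%.3f, %.3f]  p = %.3g  (n = %d)\n",
              x$icc, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics.
#'
#' @param x nonempty numeric vector.
#' @return tibble with `median` and `iqr` (Q3 - Q1).
#' @export
median_iqr <- function(x) {
  if (length(x) == 0L) stop("median_iqr: empty input", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], iqr = q[3] - q[1])
}

#' Per-subject biomarker report
#'
#' MTV, TLG and SUV statistics of one predicted mask, plus 3D Dice and
#' signed/absolute MTV and TLG deviations when a ground-truth mask is given.
#'
#' @param mask predicted binary 3D mask.
#' @param suv SUV volume (g/ml).
#' @param spacing voxel spacing (mm).
#' @param gt_mask optional ground-truth mask.
#' @param subject_id identifier carried into the report.
#' @return one-row tibble.
#' @export
biomarker_report <- function(mask, suv, spacing, gt_mask = NULL, subject_id = NA_character_) {
  mtv_ml <- mtv(mask, spacing)
  tlg_g <- tlg(mask, suv, spacing)
  rep <- tibble::tibble(
    subject_id = subject_id,
    mtv_ml = mtv_ml,
    tlg_g = tlg_g,
    suv_mean = if (sum(mask == 1) > 0) mean(suv[mask == 1]) else NA_real_,
    suv_max = if (sum(mask == 1) > 0) max(suv[mask == 1]) else NA_real_
  )
  if (!is.null(gt_mask)) {
    rep$dice <- dice3d(gt_mask, mask)
    rep$mtv_true <- mtv(gt_mask, spacing)
    rep$tlg_true <- tlg(gt_mask, suv, spacing)
    rep$mtv_dev <- abs(rep$mtv_ml - rep$mtv_true)
    rep$tlg_dev <- abs(rep$tlg_g - rep$tlg_true)
    rep$mtv_dev_signed <- rep$mtv_ml - rep$mtv_true
    rep$tlg_dev_signed <- rep$tlg_g - rep$tlg_true
  }
  rep
}

#' Evaluate segmentation methods over a cohort
#'
#' Assembles per-slice predictions into subject volumes and reports, for
#' each subject and method, the 3D Dice against ground truth plus predicted
#' and true MTV/TLG and their deviations (absolute deviation is the primary
#' summary; signed deviation is also emitted).
#'
#' @param pred named list: method -> named list of subject 3D masks.
#' @param volumes named list of `volume_sample` objects keyed by subject id.
#' @return tibble with one row per subject x method.
#' @export
evaluate_cohort <- function(pred, volumes) {
  rows <- list()
  for (method in names(pred)) {
    for (sid in names(pred[[method]])) {
      v <- volumes[[sid]]
      r <- biomarker_report(pred[[method]][[sid]], v$pet_suv, v$voxel_spacing,
                            gt_mask = v$gt_mask, subject_id = sid)
      r$method <- method
      rows[[length(rows) + 1L]] <- r
    }
  }
  dplyr::relocate(dplyr::bind_rows(rows), "method")
}

#' Method-by-biomarker ICC table
#'
#' ICC(2,1) agreement between true and predicted MTV and TLG per method,
#' with 95% CIs and p-values.
#'
#' @param reports output of [evaluate_cohort()].
#' @return tibble: method, biomarker, icc, ci_low, ci_high, p_value.
#' @export
icc_table <- function(reports) {
  out <- list()
  for (method in unique(reports$method)) {
    r <- reports[reports$method == method, ]
    for (bm in c("mtv", "tlg")) {
      ic <- tryCatch(
        icc_agreement(r[[paste0(bm, "_true")]], r[[if (bm == "mtv") "mtv_ml" else "tlg_g"]]),
        error = function(e) NULL)
      out[[length(out) + 1L]] <- tibble::tibble(
        method = method, biomarker = toupper(bm),
        icc = if (is.null(ic)) NA_real_ else ic$icc,
        ci_low = if (is.null(ic)) NA_real_ else ic$ci_low,
        ci_high = if (is.null(ic)) NA_real_ else ic$ci_high,
        p_value = if (is.null(ic)) NA_real_ else ic$p_value)
    }
  }
  dplyr::bind_rows(out)
}
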