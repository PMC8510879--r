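# Class activation maps: four methods sharing one output contract -- an
# (H, W) map over the last-conv feature grid, min-max normalized to [0, 1]
# (all-zero when the raw map is constant). Gradients are taken on the
# pre-softmax score of the target class; softmax saturation would otherwise
# drive post-softmax gradients to zero on confident slices.

#' Min-max normalize a raw activation map
#'
#' `(x - min) / (max - min)`; a constant map normalizes to all zeros so a
#' CAM threshold in `[0.1, 0.9]` is meaningful for every method.
#'
#' @param raw finite numeric matrix.
#' @return matrix with values in `[0, 1]` (argmax preserved), or all zeros.
#' @export
normalize_map <- function(raw) {
  if (!all(is.finite(raw))) stop("normalize_map: map must be finite", call. = FALSE)
  rng <- range(raw)
  if (rng[1] == rng[2]) return(array(0, dim(raw)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

new_activation_map <- function(values, method, class_index, raw = NULL) {
  structure(list(values = values, method = method, class_index = class_index,
                 raw = raw), class = "activation_map")
}

#' Classic CAM
#'
#' For architectures with a global-average-pooling + single fully connected
#' head, the class activation map is the dot product between the last-conv
#' feature maps and the FC weights of the target class:
#' `M^c = sum_k w^c_k A^k`, then min-max normalized.
#'
#' @param model a trained `tumor_classifier` with a GAP+FC head.
#' @param slice one slice record.
#' @param class_index target class (2 = tumor).
#' @return an `activation_map`.
#' @export
cam_classic <- function(model, slice, class_index = 2L) {
  w <- fc_weights(model)[, class_index] # errors on unsupported architectures
  a <- feature_maps(model, slice)
  raw <- apply_channel_weights(a, w)
  new_activation_map(normalize_map(raw), "cam", class_index, raw)
}

# sum_k w_k * A[, , k]
apply_channel_weights <- function(a, w) {
  d <- dim(a)
  array(matrix(a, d[1] * d[2], d[3]) %*% w, d[1:2])
}

#' GradCAM
#'
#' Per-channel weights are the global-average-pooled gradients of the class
#' score with respect to the last-conv feature maps,
#' `delta^c_k = (1/N) sum_hw d y^c / d A^k_hw`; the map is
#' `max(sum_k delta^c_k A^k, 0)`, min-max normalized. Works for any
#' architecture that exposes those gradients.
#'
#' @inheritParams cam_classic
#' @return an `activation_map`.
#' @export
grad_cam <- function(model, slice, class_index = 2L) {
  sg <- score_grads(model, slice, class_index)
  delta <- apply(sg$grad, 3L, mean)
  raw <- pmax(apply_channel_weights(sg$A, delta), 0)
  new_activation_map(normalize_map(raw), "gradcam", class_index, raw)
}

#' GradCAM++
#'
#' Channel weights accumulate only non-negative gradients, weighted by
#' location-specific coefficients
#' `alpha_hwk = g2_hwk / (2 g2_hwk + (sum_ij A^k_ij) g3_hwk)` built from the
#' diagonal second and third derivatives of the score transform with respect
#' to each feature-map element. The derivatives are taken with respect to
#' the exponential of the class logit: for the GAP+FC head the raw logit is
#' linear in `A`, its higher derivatives vanish, and the alpha expression
#' degenerates to 0/0, while under the exponential they have the closed
#' forms `g2 = e^y g^2`, `g3 = e^y g^3` (with `g` the first logit gradient).
#' Locations where the denominator is still zero fall back to the uniform
#' weight `1/N`. The map is `max(sum_k w_k A^k, 0)`, normalized; the overall
#' positive factor `e^y` cancels in alpha and is absorbed by normalization.
#'
#' @inheritParams cam_classic
#' @return an `activation_map`.
#' @export
grad_cam_pp <- function(model, slice, class_index = 2L) {
  sg <- score_grads(model, slice, class_index)
  g <- sg$grad
  d <- dim(g)
  n_spatial <- d[1] * d[2]
  g2 <- g^2
  g3 <- g^3
  sum_a <- apply(sg$A, 3L, sum)
  denom <- 2 * g2 + sweep(g3, 3L, sum_a, "*")
  alpha <- array(1 / n_spatial, d)
  nz <- denom != 0
  alpha[nz] <- g2[nz] / denom[nz]
  wk <- apply(alpha * pmax(g, 0), 3L, sum)
  raw <- pmax(apply_channel_weights(sg$A, wk), 0)
  new_activation_map(normalize_map(raw), "gradcam++", class_index, raw)
}

#' ScoreCAM
#'
#' Gradient-free: each feature map is upsampled to the input size
#' (bilinear), min-max normalized, and applied multiplicatively to both
#' input channels; the target-class scores of these masked inputs, softmaxed
#' over channels, weight the linear combination
#' `M^c = max(sum_k alpha^c_k A^k, 0)`, normalized. A constant
#' (unnormalizable) feature map contributes a zero mask and is handled
#' without division by zero.
#'
#' @inheritParams cam_classic
#' @param batch_size channels per forward pass; the default of 1 keeps the
#'   floating-point path identical to a one-channel-at-a-time evaluation
#'   (BLAS kernels may differ in the last ulp across batch shapes).
#' @return an `activation_map`.
#' @export
score_cam <- function(model, slice, class_index = 2L, batch_size = 1L) {
  slice <- as_one_slice(slice)
  a <- feature_maps(model, slice)
  k <- dim(a)[3]
  if (k < 1L) stop("score_cam: model exposes no feature maps", call. = FALSE)
  x <- slice_input(slice)
  h <- dim(x)[1]; w <- dim(x)[2]
  masked <- array(0, c(h, w, 2L, k))
  for (j in seq_len(k)) {
    up <- cpp_resize_bilinear(a[, , j], h, w)
    rng <- range(up)
    m <- if (rng[1] == rng[2]) array(0, c(h, w)) else (up - rng[1]) / (rng[2] - rng[1])
    masked[, , 1L, j] <- x[, , 1L] * m
    masked[, , 2L, j] <- x[, , 2L] * m
  }
  scores <- numeric(k)
  for (s in split(seq_len(k), ceiling(seq_len(k) / batch_size))) {
    out <- nn_forward(model$layers, masked[, , , s, drop = FALSE], keep_cache = FALSE)$out
    scores[s] <- out[class_index, ]
  }
  alpha <- as.numeric(softmax_cols(matrix(scores, ncol = 1L)))
  raw <- pmax(apply_channel_weights(a, alpha), 0)
  new_activation_map(normalize_map(raw), "scorecam", class_index, raw)
}

CAM_METHODS <- c("cam", "gradcam", "gradcam++", "scorecam")

#' Compute a class activation map by name
#'
#' @inheritParams cam_classic
#' @param method one of `"cam"`, `"gradcam"`, `"gradcam++"`, `"scorecam"`.
#' @return an `activation_map`.
#' @export
compute_cam <- function(model, slice, method = CAM_METHODS, class_index = 2L) {
  method <- match.arg(method)
  switch(method,
         "cam" = cam_classic(model, slice, class_index),
         "gradcam" = grad_cam(model, slice, class_index),
         "gradcam++" = grad_cam_pp(model, slice, class_index),
         "scorecam" = score_cam(model, slice, class_index))
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map %s>  %dx%d, range [%.3f, %.3f]\n", x$method,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}
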