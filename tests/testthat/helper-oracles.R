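# Independent reference implementations ("oracles") shared by the unit and
# acceptance tests. Each re-derives its quantity by the most literal route
# available -- explicit enumeration, hand-expanded formulas, or one-at-a-time
# perturbation -- never by calling the code path under test.

# per-pixel enumeration of the adaptive two-threshold routine; same
# percentile convention as the implementation (type-7, pinned by design)
segment_oracle <- function(pet, map, t_m, q_m, predicted) {
  if (!predicted) return(array(0L, dim(pet)))
  fr <- nrow(pet) / nrow(map); fc <- ncol(pet) / ncol(map)
  cand <- matrix(FALSE, nrow(pet), ncol(pet))
  for (r in seq_len(nrow(pet))) for (cl in seq_len(ncol(pet)))
    cand[r, cl] <- map[ceiling(r / fr), ceiling(cl / fc)] >= t_m
  if (!any(cand)) return(array(0L, dim(pet)))
  tq <- stats::quantile(pet[cand], q_m / 100, type = 7, names = FALSE)
  out <- array(0L, dim(pet))
  for (r in seq_len(nrow(pet))) for (cl in seq_len(ncol(pet)))
    if (cand[r, cl] && pet[r, cl] >= tq) out[r, cl] <- 1L
  out
}

stack_gt <- function(ss) {
  ss <- ss[order(ss$slice_index), ]
  array(unlist(ss$mask), c(dim(ss$mask[[1]]), nrow(ss)))
}

# exhaustive grid search by re-segmenting every subject from scratch per pair
grid_oracle <- function(model, method, slices, tm_grid, qm_grid) {
  subs <- split(slices, slices$subject_id)
  rows <- list()
  for (q in qm_grid) for (t in tm_grid) {
    dices <- vapply(subs, function(ss) {
      pred <- segment_subject(ss, model, method, cam_params(method, t, q))
      dice3d(stack_gt(ss), pred)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(t = t, q = q, d = stats::median(dices))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$d, df$t, df$q), ] # same tie-break as the implementation
  as.list(df[1, ])
}

# literal term-by-term evaluation of the GradCAM++ alpha formula with the
# hand-expanded second/third derivatives of the exponential score transform
gcpp_oracle <- function(model, slice) {
  sg <- camseg:::score_grads(model, slice, 2L)
  a <- sg$A; g <- sg$grad
  d <- dim(g)
  ey <- exp(sg$logit - sg$logit) # the uniform positive factor, kept explicit
  wk <- numeric(d[3])
  for (k in seq_len(d[3])) {
    sum_a <- sum(a[, , k])
    for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
      g2 <- ey * g[h, w, k]^2
      g3 <- ey * g[h, w, k]^3
      den <- 2 * g2 + sum_a * g3
      alpha <- if (den == 0) 1 / (d[1] * d[2]) else g2 / den
      wk[k] <- wk[k] + alpha * max(ey * g[h, w, k], 0)
    }
  }
  normalize_map(pmax(camseg:::apply_channel_weights(a, wk), 0))
}

# one-channel-at-a-time masking, forwarding and softmaxing for ScoreCAM
scorecam_oracle <- function(model, slice) {
  a <- feature_maps(model, slice)
  x <- camseg:::slice_input(slice)
  k <- dim(a)[3]
  scores <- numeric(k)
  for (j in seq_len(k)) {
    up <- camseg:::cpp_resize_bilinear(a[, , j], dim(x)[1], dim(x)[2])
    rng <- range(up)
    msk <- if (rng[1] == rng[2]) up * 0 else (up - rng[1]) / (rng[2] - rng[1])
    xm <- x
    xm[, , 1] <- x[, , 1] * msk
    xm[, , 2] <- x[, , 2] * msk
    dim(xm) <- c(dim(x), 1L)
    scores[j] <- camseg:::nn_forward(model$layers, xm, keep_cache = FALSE)$out[2, 1]
  }
  alpha <- exp(scores - max(scores)); alpha <- alpha / sum(alpha)
  normalize_map(pmax(camseg:::apply_channel_weights(a, alpha), 0))
}
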