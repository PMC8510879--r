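# Supervised 2D U-Net upper baseline: four double-convolution levels in
# encoder and decoder with skip connections between all levels, nearest
# upsampling in the decoder, and a 2-channel per-pixel softmax output
# trained with class-weighted cross entropy.

#' U-Net configuration
#'
#' Four encoder and four decoder double-convolution blocks with skip
#' connections, plus a bottleneck. Channel width doubles per level from
#' `base_channels`. Defaults follow the full-scale training recipe (Adam
#' beta1 = 0.9, beta2 = 0.999, learning rate 5e-5, batch 64, 200 epochs,
#' class weight 7.7); scale `epochs`/`base_channels` down for desk runs.
#'
#' @param input_shape (rows, cols); each side must be divisible by
#'   `2^levels`.
#' @param base_channels width of the first encoder level.
#' @param levels number of encoder/decoder levels.
#' @param epochs,learning_rate,batch_size,beta1,beta2 Adam parameters.
#' @param positive_class_weight per-pixel weight of the tumor class.
#' @param augmentation apply the same augmentation as the classifier.
#' @param seed root seed.
#' @return a validated `unet_config`.
#' @export
unet_config <- function(input_shape = c(64L, 64L), base_channels = 4L, levels = 4L,
                        epochs = 200L, learning_rate = 5e-5, batch_size = 64L,
                        beta1 = 0.9, beta2 = 0.999, positive_class_weight = 7.7,
                        augmentation = TRUE, seed = 1L) {
  cfg <- list(input_shape = as.integer(input_shape),
              base_channels = as.integer(base_channels), levels = as.integer(levels),
              epochs = as.integer(epochs), learning_rate = learning_rate,
              batch_size = as.integer(batch_size), beta1 = beta1, beta2 = beta2,
              positive_class_weight = positive_class_weight,
              augmentation = isTRUE(augmentation), seed = as.integer(seed))
  if (any(cfg$input_shape %% 2^cfg$levels != 0))
    stop("unet_config: input sides must be divisible by 2^levels", call. = FALSE)
  structure(cfg, class = "unet_config")
}

dconv_new <- function(cin, cmid) list(c1 = nn_conv(cin, cmid), c2 = nn_conv(cmid, cmid))

dconv_forward <- function(blk, x) {
  r1 <- pmax(cpp_conv3_forward(x, blk$c1$w, blk$c1$b), 0)
  r2 <- pmax(cpp_conv3_forward(r1, blk$c2$w, blk$c2$b), 0)
  list(out = r2, cache = list(x = x, r1 = r1, r2 = r2))
}

dconv_backward <- function(blk, cache, dout) {
  dy2 <- dout * (cache$r2 > 0)
  g2 <- cpp_conv3_backward(cache$r1, blk$c2$w, dy2)
  dy1 <- g2$dx * (cache$r1 > 0)
  g1 <- cpp_conv3_backward(cache$x, blk$c1$w, dy1)
  list(dx = g1$dx, g = list(c1 = list(dw = g1$dw, db = g1$db),
                            c2 = list(dw = g2$dw, db = g2$db)))
}

build_unet <- function(config, init_seed = 1L) {
  with_seed(init_seed, {
    L <- config$levels
    w <- config$base_channels * 2^(seq_len(L + 1L) - 1L)
    enc <- list(); cin <- 2L
    for (l in seq_len(L)) { enc[[l]] <- dconv_new(cin, w[l]); cin <- w[l] }
    bott <- dconv_new(w[L], w[L + 1L])
    dec <- vector("list", L)
    for (l in rev(seq_len(L))) dec[[l]] <- dconv_new(w[l + 1L] + w[l], w[l])
    final <- nn_conv(w[1L], 2L)
    # prior-logit output bias: start at the background-dominated class prior
    # so optimization spends no steps learning the constant solution first
    final$b <- c(0, -2)
    list(enc = enc, bott = bott, dec = dec, final = final, widths = w)
  })
}

unet_forward <- function(net, x, keep_cache = TRUE) {
  L <- length(net$enc)
  skips <- vector("list", L)
  caches <- list(enc = vector("list", L), pool = vector("list", L),
                 dec = vector("list", L), cat_ch = integer(L))
  cur <- x
  for (l in seq_len(L)) {
    f <- dconv_forward(net$enc[[l]], cur)
    skips[[l]] <- f$out
    if (keep_cache) caches$enc[[l]] <- f$cache
    pl <- cpp_maxpool2_forward(f$out)
    if (keep_cache) caches$pool[[l]] <- list(idx = pl$idx, dim = dim(f$out))
    cur <- pl$y
  }
  f <- dconv_forward(net$bott, cur)
  if (keep_cache) caches$bott <- f$cache
  cur <- f$out
  for (l in rev(seq_len(L))) {
    up <- cpp_upsample2_forward(cur)
    du <- dim(up); ds <- dim(skips[[l]])
    cat_in <- array(0, c(du[1], du[2], du[3] + ds[3], du[4]))
    cat_in[, , seq_len(du[3]), ] <- up
    cat_in[, , du[3] + seq_len(ds[3]), ] <- skips[[l]]
    caches$cat_ch[l] <- du[3]
    f <- dconv_forward(net$dec[[l]], cat_in)
    if (keep_cache) caches$dec[[l]] <- f$cache
    cur <- f$out
  }
  logits <- cpp_conv3_forward(cur, net$final$w, net$final$b)
  if (keep_cache) caches$final_in <- cur
  list(out = logits, caches = caches)
}

unet_backward <- function(net, caches, dlogits) {
  L <- length(net$enc)
  gf <- cpp_conv3_backward(caches$final_in, net$final$w, dlogits)
  grads <- list(final = list(dw = gf$dw, db = gf$db),
                dec = vector("list", L), enc = vector("list", L))
  dskip <- vector("list", L)
  dcur <- gf$dx
  for (l in seq_len(L)) { # decoder levels from shallowest (1) down to deepest
    b <- dconv_backward(net$dec[[l]], caches$dec[[l]], dcur)
    grads$dec[[l]] <- b$g
    cu <- caches$cat_ch[l]
    nch <- dim(b$dx)[3]
    dskip[[l]] <- b$dx[, , (cu + 1L):nch, , drop = FALSE]
    dcur <- cpp_upsample2_backward(b$dx[, , seq_len(cu), , drop = FALSE])
  }
  b <- dconv_backward(net$bott, caches$bott, dcur)
  grads$bott <- b$g
  dcur <- b$dx
  for (l in rev(seq_len(L))) { # encoder levels from deepest back to input
    dpool <- cpp_maxpool2_backward(caches$pool[[l]]$idx, dcur, caches$pool[[l]]$dim)
    b <- dconv_backward(net$enc[[l]], caches$enc[[l]], dpool + dskip[[l]])
    grads$enc[[l]] <- b$g
    dcur <- b$dx
  }
  grads
}

# flatten the nested conv blocks into a single layer list (order fixed)
unet_flat <- function(net) {
  out <- list()
  for (l in seq_along(net$enc)) { out <- c(out, net$enc[[l]][c("c1", "c2")]) }
  out <- c(out, net$bott[c("c1", "c2")])
  for (l in seq_along(net$dec)) { out <- c(out, net$dec[[l]][c("c1", "c2")]) }
  c(out, list(net$final))
}

unet_unflat <- function(net, flat) {
  i <- 1L
  for (l in seq_along(net$enc)) { net$enc[[l]]$c1 <- flat[[i]]; net$enc[[l]]$c2 <- flat[[i + 1L]]; i <- i + 2L }
  net$bott$c1 <- flat[[i]]; net$bott$c2 <- flat[[i + 1L]]; i <- i + 2L
  for (l in seq_along(net$dec)) { net$dec[[l]]$c1 <- flat[[i]]; net$dec[[l]]$c2 <- flat[[i + 1L]]; i <- i + 2L }
  net$final <- flat[[i]]
  net
}

unet_flat_grads <- function(net, grads) {
  out <- list()
  for (l in seq_along(net$enc)) out <- c(out, grads$enc[[l]][c("c1", "c2")])
  out <- c(out, grads$bott[c("c1", "c2")])
  for (l in seq_along(net$dec)) out <- c(out, grads$dec[[l]][c("c1", "c2")])
  c(out, list(grads$final))
}

#' Train the supervised U-Net baseline
#'
#' Per-pixel class-weighted softmax cross entropy minimized with Adam; the
#' weights of the best-validation-loss epoch are returned (final weights,
#' with a warning, when no validation set is given). Requires ground-truth
#' masks on every training slice -- this is the fully supervised upper
#' baseline.
#'
#' @param train,val slice tibbles with `mask` list-columns.
#' @param config a [unet_config()].
#' @param verbose print per-epoch losses.
#' @return a `unet_fit` (network, config, history tibble).
#' @export
train_unet <- function(train, val = NULL, config = unet_config(), verbose = FALSE) {
  if (!"mask" %in% names(train) || any(vapply(train$mask, is.null, logical(1))))
    stop("train_unet: ground-truth masks are required for supervised training", call. = FALSE)
  if (all(vapply(train$mask, function(m) all(m == 0), logical(1))))
    warning("train_unet: degenerate labels (all-background masks); the model will predict empty masks",
            call. = FALSE)
  net <- build_unet(config, init_seed = config$seed)
  with_seed(config$seed + 1L, {
    flat <- unet_flat(net)
    opt <- opt_init(flat, "adam", lr = config$learning_rate,
                    beta1 = config$beta1, beta2 = config$beta2)
    n <- nrow(train)
    h <- nrow(train$pet[[1]]); w <- ncol(train$pet[[1]])
    has_val <- !is.null(val) && nrow(val) > 0L
    if (has_val) {
      x_val <- make_input_batch(val)
      m_val <- array(unlist(val$mask), c(h, w, nrow(val)))
    }
    best_val <- Inf; best_net <- NULL
    hist <- list()
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (bi in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        x <- array(0, c(h, w, 2L, length(bi)))
        msk <- array(0, c(h, w, length(bi)))
        for (j in seq_along(bi)) {
          sl <- list(pet = train$pet[[bi[j]]], ct = train$ct[[bi[j]]],
                     mask = train$mask[[bi[j]]])
          if (config$augmentation)
            sl <- augment_slice(sl, seed = sample.int(.Machine$integer.max - 1L, 1L))
          x[, , , j] <- slice_input(sl)
          msk[, , j] <- sl$mask
        }
        fw <- unet_forward(net, x)
        l <- weighted_ce_pixel(fw$out, msk, config$positive_class_weight)
        grads <- unet_backward(net, fw$caches, l$dlogits)
        st <- opt_step(opt, unet_flat(net), unet_flat_grads(net, grads))
        opt <- st$opt
        net <- unet_unflat(net, st$layers)
        losses <- c(losses, l$loss)
      }
      val_loss <- NA_real_
      if (has_val) {
        lv <- 0; nv <- nrow(val); bs <- 32L
        for (s in split(seq_len(nv), ceiling(seq_len(nv) / bs))) {
          out <- unet_forward(net, x_val[, , , s, drop = FALSE], keep_cache = FALSE)$out
          lv <- lv + weighted_ce_pixel(out, m_val[, , s, drop = FALSE],
                                       config$positive_class_weight)$loss * length(s)
        }
        val_loss <- lv / nv
        if (val_loss < best_val) { best_val <- val_loss; best_net <- net }
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses), val_loss = val_loss)
      if (verbose) message(sprintf("unet epoch %d: train %.4f val %.4f", ep, mean(losses), val_loss))
    }
    if (has_val && !is.null(best_net)) {
      net <- best_net
    } else if (!has_val) {
      warning("train_unet: no validation set; returning final-epoch weights", call. = FALSE)
    }
    structure(list(net = net, config = config, history = dplyr::bind_rows(hist)),
              class = "unet_fit")
  })
}

#' Predict a per-pixel mask with a trained U-Net
#'
#' Per-pixel argmax over the two class channels; output has the input's
#' in-plane shape.
#'
#' @param fit a `unet_fit`.
#' @param slice one slice record.
#' @return binary matrix.
#' @export
predict_unet <- function(fit, slice) {
  slice <- as_one_slice(slice)
  x <- slice_input(slice)
  if (any(dim(x)[1:2] %% 2^fit$config$levels != 0))
    stop("predict_unet: slice shape incompatible with the pooling depth", call. = FALSE)
  dim(x) <- c(dim(x), 1L)
  logits <- unet_forward(fit$net, x, keep_cache = FALSE)$out
  matrix(as.integer(logits[, , 2L, 1L] > logits[, , 1L, 1L]), dim(x)[1], dim(x)[2])
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit>  %d levels, base width %d, trained %d epochs\n",
              x$config$levels, x$config$base_channels,
              if (is.null(x$history)) 0L else max(x$history$epoch)))
  invisible(x)
}
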