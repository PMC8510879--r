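# Compact CNN engine: 3x3 conv / ReLU / 2x2 max-pool / global-average-pool /
# dense layers with manual backpropagation, plus SGD-momentum and Adam.
# Feature tensors are arrays (H, W, C, N); dense activations are matrices (K, N).
# All gradients are exercised against finite differences in the test suite.

nn_conv <- function(cin, cout) {
  w <- array(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
             dim = c(3L, 3L, cin, cout))
  list(type = "conv", w = w, b = numeric(cout))
}

nn_relu <- function() list(type = "relu")
nn_pool <- function() list(type = "pool")
nn_gap <- function() list(type = "gap")

nn_dense <- function(kin, kout) {
  list(type = "dense",
       w = matrix(stats::rnorm(kin * kout, sd = sqrt(2 / kin)), kin, kout),
       b = numeric(kout))
}

# forward through layers[from:length(layers)]; returns activations and caches
nn_forward <- function(layers, x, from = 1L, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq(from, length.out = length(layers) - from + 1L)) {
    ly <- layers[[i]]
    cache <- NULL
    if (ly$type == "conv") {
      cache <- x
      x <- cpp_conv3_forward(x, ly$w, ly$b)
    } else if (ly$type == "relu") {
      x <- pmax(x, 0)
      cache <- x # output is enough: dx = dy * (out > 0)
    } else if (ly$type == "pool") {
      pl <- cpp_maxpool2_forward(x)
      cache <- list(idx = pl$idx, dim = dim(x))
      x <- pl$y
    } else if (ly$type == "gap") {
      cache <- dim(x)
      d <- dim(x)
      x <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
    } else if (ly$type == "dense") {
      cache <- x
      x <- crossprod(ly$w, x) + ly$b
    } else {
      stop("unknown layer type: ", ly$type)
    }
    if (keep_cache) caches[[i]] <- cache
  }
  list(out = x, caches = caches)
}

# backprop from dout at the output of layers[[length(layers)]] down to `from`;
# returns gradient wrt the subnet input and per-layer parameter gradients
nn_backward <- function(layers, caches, dout, from = 1L) {
  grads <- vector("list", length(layers))
  for (i in rev(seq(from, length.out = length(layers) - from + 1L))) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      g <- cpp_conv3_backward(caches[[i]], ly$w, dout)
      grads[[i]] <- list(dw = g$dw, db = g$db)
      dout <- g$dx
    } else if (ly$type == "relu") {
      dout <- dout * (caches[[i]] > 0)
    } else if (ly$type == "pool") {
      dout <- cpp_maxpool2_backward(caches[[i]]$idx, dout, caches[[i]]$dim)
    } else if (ly$type == "gap") {
      d <- caches[[i]]
      n_spatial <- d[1] * d[2]
      dx <- array(0, dim = d)
      # each spatial position receives dy / (H*W)
      dx[] <- rep(as.vector(dout) / n_spatial, each = n_spatial)
      dout <- dx
    } else if (ly$type == "dense") {
      x <- caches[[i]]
      grads[[i]] <- list(dw = x %*% t(dout), db = rowSums(dout))
      dout <- ly$w %*% dout
    }
  }
  list(dx = dout, grads = grads)
}

# ---- losses -----------------------------------------------------------------

softmax_cols <- function(z) {
  z <- exp(sweep(z, 2, apply(z, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

# class-weighted softmax cross entropy; logits (2, N), y in {0,1};
# loss averaged by total sample weight (tumor class carries weight w_pos)
weighted_ce <- function(logits, y, w_pos) {
  p <- softmax_cols(logits)
  wts <- ifelse(y == 1, w_pos, 1)
  sw <- sum(wts)
  eps <- 1e-12
  loss <- -sum(wts * log(pmax(p[cbind(y + 1L, seq_along(y))], eps))) / sw
  onehot <- matrix(0, 2, length(y))
  onehot[cbind(y + 1L, seq_along(y))] <- 1
  dlogits <- sweep(p - onehot, 2, wts, "*") / sw
  list(loss = loss, dlogits = dlogits)
}

# per-pixel weighted softmax cross entropy for 2-channel segmentation logits
# logits (H, W, 2, N), masks (H, W, N) binary
weighted_ce_pixel <- function(logits, masks, w_pos) {
  l0 <- logits[, , 1L, , drop = FALSE]
  l1 <- logits[, , 2L, , drop = FALSE]
  dim(l0) <- dim(l1) <- dim(l0)[c(1, 2, 4)]
  m <- pmax(l0, l1)
  e0 <- exp(l0 - m); e1 <- exp(l1 - m)
  z <- e0 + e1
  p1 <- e1 / z
  wts <- ifelse(masks == 1, w_pos, 1)
  sw <- sum(wts)
  eps <- 1e-12
  loss <- -sum(wts * ifelse(masks == 1, log(pmax(p1, eps)), log(pmax(1 - p1, eps)))) / sw
  d1 <- wts * (p1 - masks) / sw
  dlogits <- array(0, dim = dim(logits))
  dlogits[, , 1L, ] <- -d1
  dlogits[, , 2L, ] <- d1
  list(loss = loss, dlogits = dlogits)
}

# ---- optimizers -------------------------------------------------------------

opt_init <- function(layers, method = c("sgd", "adam"), lr = 1e-3,
                     momentum = 0.9, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  method <- match.arg(method)
  state <- lapply(layers, function(ly) {
    if (is.null(ly$w)) return(NULL)
    z <- list(vw = ly$w * 0, vb = ly$b * 0)
    if (method == "adam") z <- c(z, list(mw = ly$w * 0, mb = ly$b * 0))
    z
  })
  list(method = method, lr = lr, momentum = momentum, beta1 = beta1,
       beta2 = beta2, eps = eps, t = 0L, state = state)
}

opt_step <- function(opt, layers, grads) {
  opt$t <- opt$t + 1L
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- opt$state[[i]]
    if (opt$method == "sgd") {
      s$vw <- opt$momentum * s$vw - opt$lr * g$dw
      s$vb <- opt$momentum * s$vb - opt$lr * g$db
      layers[[i]]$w <- layers[[i]]$w + s$vw
      layers[[i]]$b <- layers[[i]]$b + s$vb
    } else {
      s$mw <- opt$beta1 * s$mw + (1 - opt$beta1) * g$dw
      s$mb <- opt$beta1 * s$mb + (1 - opt$beta1) * g$db
      s$vw <- opt$beta2 * s$vw + (1 - opt$beta2) * g$dw^2
      s$vb <- opt$beta2 * s$vb + (1 - opt$beta2) * g$db^2
      bc1 <- 1 - opt$beta1^opt$t
      bc2 <- 1 - opt$beta2^opt$t
      layers[[i]]$w <- layers[[i]]$w - opt$lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + opt$eps)
      layers[[i]]$b <- layers[[i]]$b - opt$lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + opt$eps)
    }
    opt$state[[i]] <- s
  }
  list(opt = opt, layers = layers)
}
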