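# Slice-level binary tumor classifier: a VGG-style stack of 3x3 conv blocks
# with max-pooling between blocks, closed by global average pooling and a
# single fully connected layer -- the architecture class required by classic
# CAM. PET (SUV) and CT (HU) slices form the two input channels.

SUV_CAP <- 15
HU_CAP <- 1024

#' Slice classifier architecture configuration
#'
#' VGG-style backbone: `length(channels_per_block)` convolution blocks
#' (each a vector of 3x3-conv output widths), 2x2 max pooling between
#' consecutive blocks, global average pooling after the last block and one
#' fully connected layer to the 2 class scores. `drop_first_pool` removes
#' the pooling step after the first block, doubling the side length of the
#' final feature map (with 256-input, 5-block VGG-16 geometry this yields
#' 32 x 32 feature maps). `head_hidden` inserts hidden dense layers between
#' pooling and the class scores; classic CAM then becomes unavailable while
#' the gradient-based methods still apply.
#'
#' @param input_shape (rows, cols) of the input slices.
#' @param channels_per_block list of per-block conv widths; defaults to a
#'   compact 4-block net for 64 x 64 inputs (8x8 final feature maps, K = 16).
#' @param drop_first_pool drop the pooling layer after the first block.
#' @param input_channels number of input channels (PET + CT = 2).
#' @param head_hidden integer vector of hidden dense widths (empty = GAP+FC).
#' @return A validated `classifier_config`.
#' @export
classifier_config <- function(input_shape = c(64L, 64L),
                              channels_per_block = list(8L, c(8L, 8L), c(16L, 16L), c(16L, 16L)),
                              drop_first_pool = FALSE,
                              input_channels = 2L,
                              head_hidden = integer(0)) {
  cfg <- list(input_shape = as.integer(input_shape),
              channels_per_block = lapply(channels_per_block, as.integer),
              drop_first_pool = isTRUE(drop_first_pool),
              input_channels = as.integer(input_channels),
              head_hidden = as.integer(head_hidden))
  side <- feature_map_side(cfg$input_shape[1], length(cfg$channels_per_block),
                           cfg$drop_first_pool)
  side2 <- feature_map_side(cfg$input_shape[2], length(cfg$channels_per_block),
                            cfg$drop_first_pool)
  if (side < 1 || side != round(side) || side2 != round(side2))
    stop("classifier_config: input shape incompatible with the pooling depth", call. = FALSE)
  cfg$feature_shape <- c(as.integer(side), as.integer(side2))
  structure(cfg, class = "classifier_config")
}

#' Final feature-map side length
#'
#' `input_side / 2^p` where `p` is the number of retained pooling layers:
#' one pool between consecutive conv blocks, minus one if the first pool is
#' dropped.
#'
#' @param input_side input side length in pixels.
#' @param n_blocks number of conv blocks.
#' @param drop_first_pool whether the first pooling layer is removed.
#' @return side length of the last conv block's feature maps.
#' @export
feature_map_side <- function(input_side, n_blocks, drop_first_pool = FALSE) {
  n_pool <- (n_blocks - 1L) - as.integer(drop_first_pool)
  input_side / 2^n_pool
}

#' Build an (untrained) slice classifier
#'
#' @param config a [classifier_config()].
#' @param init_seed seed for the weight initialization.
#' @return A `tumor_classifier` handle exposing, through the accessor
#'   functions, class probabilities, last-conv feature maps, gradients of the
#'   class score with respect to those maps, and (for the GAP+FC head) the
#'   fully connected class weights.
#' @export
build_classifier <- function(config = classifier_config(), init_seed = 1L) {
  if (!inherits(config, "classifier_config")) stop("config must be a classifier_config", call. = FALSE)
  with_seed(init_seed, {
    layers <- list()
    cin <- config$input_channels
    nb <- length(config$channels_per_block)
    for (b in seq_len(nb)) {
      for (ch in config$channels_per_block[[b]]) {
        layers <- c(layers, list(nn_conv(cin, ch), nn_relu()))
        cin <- ch
      }
      if (b < nb && !(b == 1L && config$drop_first_pool))
        layers <- c(layers, list(nn_pool()))
    }
    feature_index <- length(layers) # output of the last block's ReLU = A^k
    layers <- c(layers, list(nn_gap()))
    kin <- cin
    for (hh in config$head_hidden) {
      layers <- c(layers, list(nn_dense(kin, hh), nn_relu()))
      kin <- hh
    }
    layers <- c(layers, list(nn_dense(kin, 2L)))
    structure(list(layers = layers, feature_index = feature_index,
                   config = config, n_feature_maps = cin,
                   threshold = 0.5, history = NULL),
              class = "tumor_classifier")
  })
}

is_gap_fc_head <- function(model) {
  head <- model$layers[(model$feature_index + 1L):length(model$layers)]
  length(head) == 2L && head[[1]]$type == "gap" && head[[2]]$type == "dense"
}

#' Fully connected class weights of a GAP+FC classifier
#'
#' @param model a `tumor_classifier` with a global-average-pool + single
#'   fully-connected head.
#' @return matrix (K feature maps x 2 classes) of weights `w^c_k`.
#' @export
fc_weights <- function(model) {
  if (!is_gap_fc_head(model))
    stop("unsupported architecture: classic CAM requires a GAP + single FC head", call. = FALSE)
  model$layers[[length(model$layers)]]$w
}

# normalize a slice into the (H, W, 2) network input
slice_input <- function(slice) {
  pet <- pmin(pmax(slice$pet, 0), SUV_CAP) / SUV_CAP
  ct <- pmin(pmax(slice$ct, -HU_CAP), HU_CAP) / HU_CAP
  array(c(pet, ct), dim = c(dim(pet), 2L))
}

# rows of a slice tibble -> normalized batch (H, W, 2, N)
make_input_batch <- function(slices) {
  n <- nrow(slices)
  h <- nrow(slices$pet[[1]]); w <- ncol(slices$pet[[1]])
  x <- array(0, c(h, w, 2L, n))
  for (i in seq_len(n))
    x[, , , i] <- slice_input(list(pet = slices$pet[[i]], ct = slices$ct[[i]]))
  x
}

as_one_slice <- function(slice) {
  if (is.data.frame(slice)) slice <- list(pet = slice$pet[[1]], ct = slice$ct[[1]])
  slice
}

# forward a normalized batch; returns softmax probabilities (2 x N)
classifier_probs <- function(model, x) {
  softmax_cols(nn_forward(model$layers, x, keep_cache = FALSE)$out)
}

#' Last-conv feature maps for one slice
#'
#' @param model a trained `tumor_classifier`.
#' @param slice a slice record (one tibble row or `list(pet=, ct=)`).
#' @return array (H, W, K) of post-activation feature maps `A^k`.
#' @export
feature_maps <- function(model, slice) {
  slice <- as_one_slice(slice)
  x <- slice_input(slice)
  dim(x) <- c(dim(x), 1L)
  a <- nn_forward(model$layers[seq_len(model$feature_index)], x, keep_cache = FALSE)$out
  array(a, dim = dim(a)[1:3])
}

# feature maps A, class logits, and d(logit_c)/dA via backprop through the head
score_grads <- function(model, slice, class_index = 2L) {
  slice <- as_one_slice(slice)
  x <- slice_input(slice)
  dim(x) <- c(dim(x), 1L)
  fw <- nn_forward(model$layers, x, keep_cache = TRUE)
  logits <- fw$out
  # the feature layer is a ReLU, whose cache is its own output A
  a_arr <- fw$caches[[model$feature_index]]
  dout <- matrix(0, 2L, 1L)
  dout[class_index, 1L] <- 1
  bw <- nn_backward(model$layers, fw$caches, dout, from = model$feature_index + 1L)
  list(A = array(a_arr, dim = dim(a_arr)[1:3]),
       grad = array(bw$dx, dim = dim(bw$dx)[1:3]),
       logit = logits[class_index, 1L])
}

#' Predict tumor probability for slices
#'
#' @param object a trained `tumor_classifier`.
#' @param slices slice tibble (from [extract_slices()]).
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return the slice tibble's id columns plus `prob_tumor` and `pred_label`
#'   (probability >= 0.5 called tumor).
#' @export
predict.tumor_classifier <- function(object, slices, batch_size = 128L, ...) {
  n <- nrow(slices)
  probs <- numeric(n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    x <- make_input_batch(slices[s, ])
    probs[s] <- classifier_probs(object, x)[2L, ]
  }
  tibble::tibble(subject_id = slices$subject_id,
                 slice_index = slices$slice_index,
                 prob_tumor = probs,
                 pred_label = as.integer(probs >= object$threshold))
}

#' Training hyperparameters for the slice classifier
#'
#' Defaults follow the full-scale training recipe (SGD, momentum 0.9,
#' learning rate 0.001, batch size 64, 50 epochs, class weight 7.7 on the
#' tumor class of the cross entropy, augmentation on); scale `epochs` down
#' for desk-scale runs.
#'
#' @param epochs,learning_rate,batch_size,momentum SGD parameters.
#' @param positive_class_weight weight of the tumor class in the loss.
#' @param augmentation apply random scale/rotation/translation/contrast.
#' @param optimizer `"sgd"` (momentum SGD, the reference recipe) or
#'   `"adam"`; at small training scales Adam escapes the initial
#'   constant-prediction plateau in far fewer steps.
#' @param seed root seed for init, shuffling and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, learning_rate = 0.001, batch_size = 64L,
                         momentum = 0.9, positive_class_weight = 7.7,
                         augmentation = TRUE, optimizer = c("sgd", "adam"),
                         seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), learning_rate = learning_rate,
              batch_size = as.integer(batch_size), momentum = momentum,
              positive_class_weight = positive_class_weight,
              augmentation = isTRUE(augmentation),
              optimizer = match.arg(optimizer), seed = as.integer(seed))
  stopifnot(cfg$epochs >= 1, cfg$learning_rate > 0, cfg$batch_size >= 1,
            cfg$positive_class_weight > 0)
  structure(cfg, class = "train_config")
}

#' Randomly augment one slice
#'
#' Random in-plane scaling, rotation and translation applied identically to
#' both channels (bilinear) and to the mask (nearest neighbour), plus a
#' per-channel multiplicative contrast jitter. The slice label is unchanged.
#' Deterministic given `seed`; `params` overrides sampling (identity
#' parameters reproduce the input exactly).
#'
#' @param slice one slice record (tibble row or list with `pet`, `ct`,
#'   optional `mask`).
#' @param seed integer seed used to sample the transform.
#' @param params optional list(scale, angle, shift, contrast_pet, contrast_ct).
#' @return the slice record with transformed channels.
#' @export
augment_slice <- function(slice, seed = NULL, params = NULL) {
  row <- is.data.frame(slice)
  sl <- if (row) as.list(slice[1, ]) else slice
  pet <- if (row) sl$pet[[1]] else sl$pet
  ct <- if (row) sl$ct[[1]] else sl$ct
  mask <- if (row) sl$mask[[1]] else sl$mask
  if (is.null(params)) {
    params <- with_seed(seed, list(scale = stats::runif(1, 0.9, 1.1),
                                   angle = stats::runif(1, -15, 15),
                                   shift = stats::runif(2, -3, 3),
                                   contrast_pet = stats::runif(1, 0.9, 1.1),
                                   contrast_ct = stats::runif(1, 0.9, 1.1)))
  }
  h <- nrow(pet); w <- ncol(pet)
  ctr <- c((h - 1) / 2, (w - 1) / 2)
  th <- params$angle * pi / 180
  # inverse map: dst -> src = R(-theta)/s %*% (dst - ctr - shift) + ctr
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) / params$scale
  off <- ctr - rot %*% (ctr + params$shift)
  m <- cbind(rot, off)
  chans <- array(c(pet, ct), c(h, w, 2L))
  warped <- cpp_warp_affine(chans, m, TRUE)
  pet2 <- warped[, , 1] * params$contrast_pet
  ct2 <- warped[, , 2] * params$contrast_ct
  mask2 <- if (!is.null(mask)) {
    mm <- array(mask, c(h, w, 1L))
    array(as.integer(round(cpp_warp_affine(mm, m, FALSE))), c(h, w))
  }
  if (row) {
    slice$pet[[1]] <- pet2; slice$ct[[1]] <- ct2
    if (!is.null(mask)) slice$mask[[1]] <- mask2
    slice
  } else {
    sl$pet <- pet2; sl$ct <- ct2
    if (!is.null(mask)) sl$mask <- mask2
    sl
  }
}

#' Train the slice classifier
#'
#' Weighted softmax cross entropy (weight `positive_class_weight` on the
#' tumor class) minimized by SGD with momentum. The returned handle carries
#' the weights of the epoch with the best validation loss (paper-silent
#' model selection: best validation loss); with an empty validation set the
#' final-epoch weights are returned with a warning. Training history is a
#' tibble in `$history`.
#'
#' @param train,val slice tibbles (see [extract_slices()]); `train` must
#'   contain both classes.
#' @param config a [classifier_config()].
#' @param tconfig a [train_config()].
#' @param verbose print per-epoch losses.
#' @return a trained `tumor_classifier`.
#' @export
train_classifier <- function(train, val = NULL, config = classifier_config(),
                             tconfig = train_config(), verbose = FALSE) {
  if (length(unique(train$label)) < 2L)
    stop("train_classifier: training set must contain both classes", call. = FALSE)
  model <- build_classifier(config, init_seed = tconfig$seed)
  with_seed(tconfig$seed + 1L, {
    opt <- opt_init(model$layers, tconfig$optimizer, lr = tconfig$learning_rate,
                    momentum = tconfig$momentum)
    n <- nrow(train)
    has_val <- !is.null(val) && nrow(val) > 0L
    x_val <- if (has_val) make_input_batch(val)
    best_val <- Inf
    best_layers <- NULL
    hist <- list()
    for (ep in seq_len(tconfig$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      h <- nrow(train$pet[[1]]); w <- ncol(train$pet[[1]])
      for (bi in split(ord, ceiling(seq_along(ord) / tconfig$batch_size))) {
        x <- array(0, c(h, w, 2L, length(bi)))
        for (j in seq_along(bi)) {
          sl <- list(pet = train$pet[[bi[j]]], ct = train$ct[[bi[j]]])
          if (tconfig$augmentation)
            sl <- augment_slice(sl, seed = sample.int(.Machine$integer.max - 1L, 1L))
          x[, , , j] <- slice_input(sl)
        }
        fw <- nn_forward(model$layers, x)
        l <- weighted_ce(fw$out, train$label[bi], tconfig$positive_class_weight)
        bw <- nn_backward(model$layers, fw$caches, l$dlogits)
        st <- opt_step(opt, model$layers, bw$grads)
        opt <- st$opt; model$layers <- st$layers
        losses <- c(losses, l$loss)
      }
      val_loss <- NA_real_
      if (has_val) {
        lv <- weighted_ce(nn_forward(model$layers, x_val, keep_cache = FALSE)$out,
                          val$label, tconfig$positive_class_weight)
        val_loss <- lv$loss
        if (val_loss < best_val) {
          best_val <- val_loss
          best_layers <- model$layers
        }
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                   val_loss = val_loss)
      if (verbose) message(sprintf("epoch %d: train %.4f val %.4f",
                                   ep, mean(losses), val_loss))
    }
    if (has_val && !is.null(best_layers)) {
      model$layers <- best_layers
    } else if (!has_val) {
      warning("train_classifier: no validation set; returning final-epoch weights",
              call. = FALSE)
    }
    model$history <- dplyr::bind_rows(hist)
    model$tconfig <- tconfig
    model
  })
}

#' @export
print.tumor_classifier <- function(x, ...) {
  cat(sprintf("<tumor_classifier>  %d conv feature maps (%s), head: %s, %s\n",
              x$n_feature_maps, paste(x$config$feature_shape, collapse = "x"),
              if (is_gap_fc_head(x)) "GAP+FC" else "GAP+MLP",
              if (is.null(x$history)) "untrained" else sprintf("trained %d epochs", max(x$history$epoch))))
  invisible(x)
}
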