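# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small phantom cohort (32x32x16) with high positive fraction -- fast to
# generate and enough signal to train toy models on
toy_cohort <- function() cached("toy_cohort", function() {
  cfg <- phantom_config(n_subjects = 12L, slices_per_subject = 16L,
                        slice_shape = c(32L, 32L),
                        positive_slice_fraction = 0.3,
                        lesion_size_meanlog = 3.6, seed = 421L)
  co <- generate_cohort(cfg)
  list(config = cfg, cohort = co, slices = extract_slices(co))
})

toy_classifier_config <- function(input = c(32L, 32L))
  classifier_config(input_shape = input,
                    channels_per_block = list(4L, c(8L, 8L), c(8L, 8L)))

# a trained toy classifier on the toy cohort (GAP+FC head, 8x8 feature maps)
toy_classifier <- function() cached("toy_classifier", function() {
  sl <- toy_cohort()$slices
  tr <- sl[sl$split == "train", ]
  va <- sl[sl$split == "val", ]
  train_classifier(tr, va, toy_classifier_config(),
                   train_config(epochs = 12L, learning_rate = 3e-3,
                                batch_size = 16L, optimizer = "adam",
                                augmentation = FALSE, seed = 7L))
})

# untrained tiny models for analytic/finite-difference checks
tiny_gapfc_model <- function(seed = 1L)
  build_classifier(classifier_config(input_shape = c(8L, 8L),
                                     channels_per_block = list(3L, 4L)),
                   init_seed = seed)

tiny_mlp_model <- function(seed = 1L)
  build_classifier(classifier_config(input_shape = c(8L, 8L),
                                     channels_per_block = list(3L, 4L),
                                     head_hidden = 5L),
                   init_seed = seed)

random_slice <- function(h = 8L, w = 8L, seed = 1L) {
  withr::with_seed(seed, list(pet = matrix(stats::runif(h * w, 0, 8), h, w),
                              ct = matrix(stats::rnorm(h * w, 40, 100), h, w)))
}

# sample skewness by direct moment computation
moment_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# forward the head of a classifier from given feature maps A (H, W, K)
head_forward <- function(model, a) {
  dim(a) <- c(dim(a), 1L)
  camseg:::nn_forward(model$layers, a, from = model$feature_index + 1L,
                      keep_cache = FALSE)$out
}

# central finite differences of the class-c logit wrt each feature map cell
fd_feature_grads <- function(model, slice, class_index = 2L, eps = 1e-4) {
  a <- feature_maps(model, slice)
  g <- array(0, dim(a))
  for (i in seq_along(a)) {
    ap <- a; ap[i] <- ap[i] + eps
    am <- a; am[i] <- am[i] - eps
    g[i] <- (head_forward(model, ap)[class_index, 1] -
               head_forward(model, am)[class_index, 1]) / (2 * eps)
  }
  g
}
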