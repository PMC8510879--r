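test_that("min-max normalization maps any grid into [0,1] and zeros constants", {
  expect_equal(normalize_map(matrix(c(0, 4, 2, 8), 2, 2)),
               matrix(c(0, 0.5, 0.25, 1), 2, 2))
  expect_equal(normalize_map(matrix(5, 3, 3)), array(0, c(3, 3)))
  withr::with_seed(3, {
    for (i in 1:10) {
      raw <- matrix(stats::rnorm(16, sd = 10^stats::runif(1, -3, 3)), 4, 4)
      nm <- normalize_map(raw)
      expect_gte(min(nm), 0)
      expect_lte(max(nm), 1)
      expect_identical(which.max(nm), which.max(raw))
    }
  })
  expect_error(normalize_map(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("classic CAM is the FC-weighted sum of feature maps", {
  # direct dot product on hand-built feature stacks
  a <- array(0, c(2, 2, 2))
  a[, , 1] <- matrix(c(1, 0, 0, 0), 2, 2)
  a[, , 2] <- matrix(c(0, 0, 2, 0), 2, 2)
  raw <- camseg:::apply_channel_weights(a, c(1, 0.5))
  expect_equal(raw, matrix(c(1, 0, 1, 0), 2, 2))
  # all-zero class weights give an all-zero map
  m <- tiny_gapfc_model(seed = 6L)
  m$layers[[length(m$layers)]]$w[, 2] <- 0
  cm <- cam_classic(m, random_slice(seed = 2))
  expect_equal(cm$values, array(0, dim(cm$values)))
  # unsupported architecture errors
  expect_error(cam_classic(tiny_mlp_model(), random_slice()), "unsupported")
})

test_that("GradCAM equals normalized ReLU of classic CAM on GAP+FC heads", {
  cases <- list(
    list(m = tiny_gapfc_model(seed = 7L), slice = random_slice(8, 8, seed = 1)),
    list(m = tiny_gapfc_model(seed = 7L), slice = random_slice(8, 8, seed = 2)),
    list(m = toy_classifier(), slice = random_slice(32, 32, seed = 3)),
    list(m = toy_classifier(),
         slice = toy_cohort()$slices[which(toy_cohort()$slices$label == 1)[1], ]))
  for (cs in cases) {
    gc <- grad_cam(cs$m, cs$slice)
    cc <- cam_classic(cs$m, cs$slice)
    expect_equal(gc$values, normalize_map(pmax(cc$raw, 0)), tolerance = 1e-5)
  }
})

test_that("GradCAM pooled gradients match a finite-difference oracle", {
  mm <- tiny_mlp_model(seed = 8L)
  slice <- random_slice(seed = 4)
  fd <- fd_feature_grads(mm, slice, 2L)
  delta_fd <- apply(fd, 3, mean)
  sg <- camseg:::score_grads(mm, slice, 2L)
  delta <- apply(sg$grad, 3, mean)
  expect_equal(delta, delta_fd, tolerance = 1e-3)
  raw_fd <- pmax(camseg:::apply_channel_weights(sg$A, delta_fd), 0)
  gc <- grad_cam(mm, slice)
  expect_equal(gc$values, normalize_map(raw_fd), tolerance = 1e-3)
})

test_that("GradCAM++ matches a literal term-by-term evaluation", {
  for (m in list(tiny_gapfc_model(seed = 9L), tiny_mlp_model(seed = 10L))) {
    for (s in 1:3) {
      slice <- random_slice(seed = s + 20)
      expect_equal(grad_cam_pp(m, slice)$values, gcpp_oracle(m, slice),
                   tolerance = 1e-6)
    }
  }
  # all gradients zero -> all-zero map
  m0 <- tiny_gapfc_model(seed = 11L)
  m0$layers[[length(m0$layers)]]$w[, 2] <- 0
  expect_equal(grad_cam_pp(m0, random_slice(seed = 5))$values, array(0, c(4, 4)))
})

test_that("ScoreCAM equals the one-channel-at-a-time perturbation oracle", {
  m <- tiny_gapfc_model(seed = 12L) # K = 4 feature maps
  for (s in 1:3) {
    slice <- random_slice(seed = s + 30)
    expect_equal(score_cam(m, slice)$values, scorecam_oracle(m, slice))
  }
})

test_that("ScoreCAM handles a single channel and constant feature maps", {
  m1 <- build_classifier(classifier_config(input_shape = c(8L, 8L),
                                           channels_per_block = list(2L, 1L)))
  slice <- random_slice(seed = 40)
  sc <- score_cam(m1, slice)
  a <- feature_maps(m1, slice)
  expect_equal(sc$values, normalize_map(pmax(a[, , 1], 0)))
  # zero the last conv: all feature maps constant; no NaN, all-zero map
  mz <- tiny_gapfc_model(seed = 13L)
  last_conv <- max(which(vapply(mz$layers, function(l) l$type == "conv", logical(1))))
  mz$layers[[last_conv]]$w[] <- 0
  mz$layers[[last_conv]]$b[] <- 0
  sz <- score_cam(mz, slice)
  expect_true(all(is.finite(sz$values)))
  expect_equal(sz$values, array(0, dim(sz$values)))
})

test_that("all four methods share the output contract and are deterministic", {
  m <- toy_classifier()
  slice <- toy_cohort()$slices[which(toy_cohort()$slices$label == 1)[2], ]
  for (meth in c("cam", "gradcam", "gradcam++", "scorecam")) {
    a1 <- compute_cam(m, slice, meth)
    a2 <- compute_cam(m, slice, meth)
    expect_identical(a1$values, a2$values)
    expect_identical(dim(a1$values), m$config$feature_shape)
    expect_gte(min(a1$values), 0)
    expect_lte(max(a1$values), 1)
  }
})
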