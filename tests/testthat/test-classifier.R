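test_that("feature-map geometry follows the retained pooling count", {
  # full-scale geometry: 256 input, 5 blocks, first pool dropped -> 32
  expect_equal(feature_map_side(256, 5, drop_first_pool = TRUE), 32)
  # desk geometry: 64 input, 4 blocks (3 pools) -> 8
  expect_equal(feature_map_side(64, 4), 8)
  cc <- classifier_config(input_shape = c(64, 64))
  expect_equal(cc$feature_shape, c(8L, 8L))
  expect_error(classifier_config(input_shape = c(50, 50)), "incompatible")
})

test_that("forward pass yields proper probabilities, even on a zero slice", {
  m <- tiny_gapfc_model()
  zero <- list(pet = matrix(0, 8, 8), ct = matrix(0, 8, 8),
               subject_id = "z", slice_index = 1L)
  sl <- tibble::tibble(subject_id = "z", slice_index = 1L,
                       pet = list(zero$pet), ct = list(zero$ct))
  pr <- predict(m, sl)
  expect_true(is.finite(pr$prob_tumor))
  expect_gte(pr$prob_tumor, 0)
  expect_lte(pr$prob_tumor, 1)
})

test_that("the GAP+FC head satisfies the linear class-score identity", {
  m <- tiny_gapfc_model(seed = 3L)
  w <- fc_weights(m)
  b <- m$layers[[length(m$layers)]]$b
  for (s in 1:3) {
    slice <- random_slice(seed = s)
    a <- feature_maps(m, slice)
    gap <- apply(a, 3, mean)
    manual <- drop(crossprod(w, gap)) + b
    sg <- camseg:::score_grads(m, slice, 2L)
    expect_equal(sg$logit, manual[2], tolerance = 1e-5)
  }
})

test_that("feature-map gradients are w/N for GAP+FC and match finite differences generally", {
  m <- tiny_gapfc_model(seed = 4L)
  n <- prod(m$config$feature_shape)
  w2 <- fc_weights(m)[, 2]
  sg <- camseg:::score_grads(m, random_slice(seed = 9), 2L)
  expect_equal(sg$grad, array(rep(w2 / n, each = n), dim(sg$grad)),
               tolerance = 1e-5)
  # arbitrary (nonlinear-head) architecture: central finite differences
  mm <- tiny_mlp_model(seed = 5L)
  slice <- random_slice(seed = 10)
  sg <- camseg:::score_grads(mm, slice, 2L)
  fd <- fd_feature_grads(mm, slice, 2L)
  expect_equal(sg$grad, fd, tolerance = 1e-3)
})

test_that("augmentation preserves labels, identity parameters, and determinism", {
  sl <- toy_cohort()$slices[5, ]
  idp <- list(scale = 1, angle = 0, shift = c(0, 0),
              contrast_pet = 1, contrast_ct = 1)
  out <- augment_slice(sl, params = idp)
  expect_equal(out$pet[[1]], sl$pet[[1]], tolerance = 1e-12)
  expect_equal(out$ct[[1]], sl$ct[[1]], tolerance = 1e-12)
  expect_identical(out$mask[[1]], sl$mask[[1]])
  a1 <- augment_slice(sl, seed = 42L)
  a2 <- augment_slice(sl, seed = 42L)
  expect_identical(a1, a2)
  expect_identical(a1$label, sl$label)
  expect_false(isTRUE(all.equal(a1$pet[[1]], sl$pet[[1]])))
  # mask stays binary under nearest-neighbour warping
  expect_true(all(a1$mask[[1]] %in% c(0L, 1L)))
})

test_that("training improves the loss on a separable toy problem", {
  sl <- toy_cohort()$slices
  tr <- sl[sl$split == "train", ][1:96, ]
  expect_error(train_classifier(tr[tr$label == 0, ], NULL, toy_classifier_config()),
               "both classes")
  m <- suppressWarnings(
    train_classifier(tr, NULL, toy_classifier_config(),
                     train_config(epochs = 5L, learning_rate = 3e-3,
                                  batch_size = 16L, optimizer = "adam",
                                  augmentation = FALSE, seed = 2L)))
  expect_lt(m$history$train_loss[5], m$history$train_loss[1])
  expect_warning(
    train_classifier(tr[1:48, ], NULL, toy_classifier_config(),
                     train_config(epochs = 1L, augmentation = FALSE, seed = 2L)),
    "no validation")
})

test_that("the tumor-class weight trades precision for recall", {
  # imbalanced toy set; recall with w = 7.7 should not fall below w = 1
  sl <- toy_cohort()$slices
  tr <- sl[sl$split == "train", ]
  te <- sl[sl$split == "test", ]
  recalls <- sapply(c(1, 7.7), function(w) {
    mean(sapply(1:3, function(s) {
      m <- suppressWarnings(train_classifier(
        tr, NULL, toy_classifier_config(),
        train_config(epochs = 4L, learning_rate = 3e-3, batch_size = 16L,
                     optimizer = "adam", positive_class_weight = w,
                     augmentation = FALSE, seed = s)))
      pr <- predict(m, te)
      mean(pr$pred_label[te$label == 1] == 1)
    }))
  })
  expect_gte(recalls[2], recalls[1])
})

test_that("training is deterministic under a fixed seed", {
  sl <- toy_cohort()$slices[1:48, ]
  cfgs <- list(toy_classifier_config(),
               train_config(epochs = 2L, batch_size = 16L, optimizer = "adam",
                            seed = 11L))
  m1 <- suppressWarnings(train_classifier(sl, NULL, cfgs[[1]], cfgs[[2]]))
  m2 <- suppressWarnings(train_classifier(sl, NULL, cfgs[[1]], cfgs[[2]]))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
})
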