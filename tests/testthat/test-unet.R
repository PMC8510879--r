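test_that("output shape and binariness hold for any valid input size", {
  for (side in c(16L, 32L)) {
    cfg <- unet_config(input_shape = c(side, side), base_channels = 2L,
                       epochs = 1L, seed = 3L)
    net <- camseg:::build_unet(cfg, init_seed = 3L)
    fit <- structure(list(net = net, config = cfg), class = "unet_fit")
    slice <- random_slice(side, side, seed = side)
    mk <- predict_unet(fit, slice)
    expect_identical(dim(mk), c(side, side))
    expect_true(all(mk %in% 0:1))
  }
  expect_error(unet_config(input_shape = c(24, 24), levels = 4L), "divisible")
})

test_that("an untrained net predicts one constant class on zero input", {
  cfg <- unet_config(input_shape = c(16L, 16L), base_channels = 2L, seed = 5L)
  fit <- structure(list(net = camseg:::build_unet(cfg, 5L), config = cfg),
                   class = "unet_fit")
  mk <- predict_unet(fit, list(pet = matrix(0, 16, 16), ct = matrix(0, 16, 16)))
  expect_equal(length(unique(as.vector(mk))), 1L)
})

test_that("missing or degenerate masks are handled as specified", {
  sl <- toy_cohort()$slices[1:16, ]
  nomask <- sl; nomask$mask <- NULL
  expect_error(train_unet(nomask, NULL, unet_config(input_shape = c(32, 32))),
               "masks")
  allbg <- sl
  allbg$mask <- lapply(allbg$mask, function(m) m * 0L)
  w <- capture_warnings(
    fit <- train_unet(allbg, NULL,
      unet_config(input_shape = c(32, 32), base_channels = 2L, epochs = 1L,
                  learning_rate = 1e-3, batch_size = 8L, augmentation = FALSE,
                  seed = 2L)))
  expect_true(any(grepl("degenerate labels", w)))
  # and the resulting model predicts (essentially) empty masks
  mk <- predict_unet(fit, sl[1, ])
  expect_lt(mean(mk), 0.01)
})

test_that("a scaled-down training run segments toy blobs", {
  sl <- toy_cohort()$slices
  tr <- sl[sl$split == "train", ]
  pos <- which(tr$label == 1)
  neg <- which(tr$label == 0)[seq_along(pos)]
  sub <- tr[sort(c(pos, neg)), ]
  va <- sl[sl$split == "val", ]
  dices <- sapply(1:2, function(s) {
    fit <- train_unet(sub, va, unet_config(input_shape = c(32, 32),
                                           base_channels = 4L, epochs = 8L,
                                           learning_rate = 3e-3, batch_size = 8L,
                                           augmentation = FALSE, seed = s))
    vp <- va[va$label == 1, ]
    mean(sapply(seq_len(nrow(vp)), function(i)
      dice3d(vp$mask[[i]], predict_unet(fit, vp[i, ]))))
  })
  expect_gt(stats::median(dices), 0.5)
})

test_that("training is reproducible under a fixed seed", {
  sl <- toy_cohort()$slices[1:24, ]
  cfg <- unet_config(input_shape = c(32, 32), base_channels = 2L, epochs = 2L,
                     learning_rate = 1e-3, batch_size = 8L, seed = 9L)
  f1 <- suppressWarnings(train_unet(sl, NULL, cfg))
  f2 <- suppressWarnings(train_unet(sl, NULL, cfg))
  expect_identical(f1$history, f2$history)
})
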