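test_that("tidiers and plots expose fitted objects tabularly", {
  m <- toy_classifier()
  td <- generics::tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(td)))
  gl <- generics::glance(m)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$epochs, nrow(td))
  expect_equal(gl$best_epoch, which.min(td$val_loss))

  ic <- icc_agreement(1:8 + 0.5, c(1.2, 2.1, 2.9, 4.4, 5.0, 6.2, 7.1, 7.9))
  ti <- generics::tidy(ic)
  expect_named(ti, c("estimate", "conf.low", "conf.high", "p.value", "n"))

  va <- toy_cohort()$slices
  va <- va[va$split == "val", ]
  tg <- tune_thresholds(m, "gradcam", va, tm_grid = c(0.3, 0.6), qm_grid = c(30, 45))
  expect_equal(nrow(generics::tidy(tg)), 4L)
  gb <- generics::glance(tg)
  expect_equal(gb$median_dice, max(generics::tidy(tg)$median_dice))

  slice <- va[which(va$label == 1)[1], ]
  am <- compute_cam(m, slice, "gradcam")
  p1 <- ggplot2::autoplot(am)
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(m)
  expect_s3_class(p2, "ggplot")
  p3 <- ggplot2::autoplot(tg)
  expect_s3_class(p3, "ggplot")
  p4 <- plot_slice(slice, mask = cam_segment(slice, am, cam_params("gradcam", 0.4, 40), TRUE),
                   gt_mask = slice$mask[[1]])
  expect_s3_class(p4, "ggplot")
})
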