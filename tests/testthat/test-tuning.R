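test_that("a 1x1 grid returns its only candidate pair", {
  m <- toy_classifier()
  va <- toy_cohort()$slices
  va <- va[va$split == "val", ]
  tg <- tune_thresholds(m, "gradcam", va, tm_grid = 0.4, qm_grid = 35)
  b <- attr(tg, "best")
  expect_equal(b$t_m, 0.4)
  expect_equal(b$q_m, 35)
  expect_equal(nrow(tg), 1L)
})

test_that("default grids instantiate the 20 x 10 candidate set", {
  m <- toy_classifier()
  va <- toy_cohort()$slices
  va <- va[va$split == "val", ]
  tg <- tune_thresholds(m, "cam", va)
  expect_equal(nrow(tg), 200L)
  expect_equal(sort(unique(tg$t_m)), seq(0.1, 0.9, length.out = 10))
  expect_equal(sort(unique(tg$q_m)), seq(20, 50, length.out = 20))
})

test_that("the grid search equals an independent exhaustive argmax", {
  m <- toy_classifier()
  va <- toy_cohort()$slices
  va <- va[va$split == "val", ]
  tms <- c(0.2, 0.5, 0.8); qms <- c(25, 35, 45)
  tg <- tune_thresholds(m, "gradcam++", va, tm_grid = tms, qm_grid = qms)
  b <- attr(tg, "best")
  oracle <- grid_oracle(m, "gradcam++", va, tms, qms)
  expect_equal(b$t_m, oracle$t)
  expect_equal(b$q_m, oracle$q)
  expect_equal(b$median_dice, oracle$d, tolerance = 1e-12)
  # idempotence: re-evaluating the winning pair reproduces its Dice
  redo <- vapply(split(va, va$subject_id), function(ss) {
    pred <- segment_subject(ss, m, "gradcam++", cam_params("gradcam++", b$t_m, b$q_m))
    dice3d(stack_gt(ss), pred)
  }, numeric(1))
  expect_equal(stats::median(redo), b$median_dice, tolerance = 1e-12)
})

test_that("the global-threshold search shares the machinery and conventions", {
  m <- toy_classifier()
  va <- toy_cohort()$slices
  va <- va[va$split == "val", ]
  tg <- tune_global_threshold(m, va, q_grid = c(25, 40))
  b <- attr(tg, "best")
  redo <- vapply(split(va, va$subject_id), function(ss) {
    pred <- segment_subject(ss, m, "global", list(q = b$q_m))
    dice3d(stack_gt(ss), pred)
  }, numeric(1))
  expect_equal(stats::median(redo), b$median_dice, tolerance = 1e-12)
})

test_that("degenerate validation inputs are rejected", {
  m <- toy_classifier()
  va <- toy_cohort()$slices
  va <- va[va$split == "val", ]
  expect_error(tune_thresholds(m, "cam", va, tm_grid = numeric(0)), "nonempty")
  neg <- va
  neg$mask <- lapply(neg$mask, function(x) x * 0L)
  expect_error(tune_thresholds(m, "cam", neg), "no positive")
})
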