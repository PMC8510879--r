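test_that("nearest-neighbour upscaling replicates blocks exactly", {
  g <- matrix(c(1, 0, 0, 0), 2, 2)
  up <- upscale_nearest(g, c(8, 8))
  expect_equal(sum(up), 16)
  expect_true(all(up[1:4, 1:4] == 1))
  expect_equal(upscale_nearest(g, c(2, 2)), g)
  withr::with_seed(4, {
    g <- matrix(rbinom(16, 1, 0.5), 4, 4)
    up <- upscale_nearest(g, c(32, 32))
    # per-pixel coordinate-mapping oracle
    for (r in sample(1:32, 8)) for (cl in sample(1:32, 8))
      expect_equal(up[r, cl], g[ceiling(r / 8), ceiling(cl / 8)])
  })
  expect_error(upscale_nearest(matrix(0, 3, 3), c(7, 7)), "integer multiple")
})

test_that("the worked 2x2 example matches exhaustive enumeration", {
  map <- matrix(c(0.9, 0.1, 0.2, 0.05), 2, 2, byrow = FALSE)
  pet <- matrix(0.5, 4, 4)
  pet[1:2, 1:2] <- c(1, 3, 2, 4)
  slice <- list(pet = pet)
  sm <- cam_segment(slice, map, cam_params("cam", 0.3, 50), TRUE)
  expect_equal(sm$t_q, stats::quantile(c(1, 2, 3, 4), 0.5, type = 7, names = FALSE))
  expect_equal(sm$values, segment_oracle(pet, map, 0.3, 50, TRUE))
  expect_equal(sum(sm$values), 2) # SUV 2.5 and above within the block
})

test_that("cam_segment equals the enumeration oracle on 200 random instances", {
  withr::with_seed(11, {
    n_checked <- 0L
    for (i in 1:200) {
      hw <- sample(c(2, 4), 1)
      f <- sample(c(2, 4), 1)
      pet <- matrix(stats::runif(hw * hw * f * f, 0, 10), hw * f, hw * f)
      map <- matrix(stats::runif(hw * hw), hw, hw)
      if (i %% 7 == 0) map[] <- 0 # exercise the empty-candidate branch
      t_m <- stats::runif(1, 0.05, 0.95)
      q_m <- stats::runif(1, 1, 100) # q < 1 is reserved for the fractional input convention
      predicted <- i %% 5 != 0 # exercise the negative-classification branch
      got <- suppressWarnings(
        cam_segment(list(pet = pet), map, cam_params("cam", t_m, q_m), predicted))
      expect_identical(got$values, segment_oracle(pet, map, t_m, q_m, predicted))
      n_checked <- n_checked + 1L
    }
    expect_equal(n_checked, 200L)
  })
})

test_that("raising either threshold never enlarges the mask", {
  withr::with_seed(12, {
    for (i in 1:20) {
      pet <- matrix(stats::runif(64, 0, 10), 8, 8)
      map <- matrix(stats::runif(16), 4, 4)
      tms <- sort(stats::runif(4))
      qms <- sort(stats::runif(4, 1, 100))
      # candidate region shrinks with t_m
      cands <- lapply(tms, function(t) upscale_nearest(map >= t, c(8, 8)))
      for (j in 2:4) expect_true(all(cands[[j]] <= cands[[j - 1]]))
      # final mask shrinks with q_m at fixed t_m
      masks <- lapply(qms, function(q) suppressWarnings(
        cam_segment(list(pet = pet), map, cam_params("cam", tms[2], q), TRUE))$values)
      for (j in 2:4) expect_true(all(masks[[j]] <= masks[[j - 1]]))
      # mask is always inside the upscaled candidate region
      for (j in 1:4) expect_true(all(masks[[j]] <= cands[[2]]))
    }
  })
})

test_that("the global percentile baseline matches a sort-based oracle", {
  ramp <- matrix(1:16, 4, 4)
  sm <- global_threshold_segment(list(pet = ramp), 75, TRUE)
  srt <- sort(as.numeric(ramp))
  tq <- stats::quantile(srt, 0.75, type = 7, names = FALSE)
  expect_equal(sm$values, array(as.integer(ramp >= tq), c(4, 4)))
  # q = 0 keeps every pixel; negative prediction empties the mask
  expect_true(all(global_threshold_segment(list(pet = ramp), 0, TRUE)$values == 1))
  expect_true(all(global_threshold_segment(list(pet = ramp), 50, FALSE)$values == 0))
  # fractional q is interpreted as a fraction
  expect_equal(global_threshold_segment(list(pet = ramp), 0.75, TRUE)$values,
               sm$values)
})

test_that("segmenting a subject stacks per-slice masks in slice order", {
  m <- toy_classifier()
  sl <- toy_cohort()$slices
  one <- sl[sl$subject_id == sl$subject_id[1], ]
  shuffled <- one[sample(nrow(one)), ]
  p <- cam_params("gradcam", 0.4, 40)
  v1 <- segment_subject(one, m, "gradcam", p)
  v2 <- segment_subject(shuffled, m, "gradcam", p)
  expect_identical(v1, v2)
  expect_identical(dim(v1), c(32L, 32L, 16L))
  expect_true(all(v1 %in% 0:1))
})
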