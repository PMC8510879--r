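test_that("Dice handles the closed-form and degenerate cases", {
  a <- array(0L, c(4, 4, 2)); a[1:2, 1:2, 1] <- 1L
  expect_equal(dice3d(a, a), 1)
  b <- array(0L, c(4, 4, 2)); b[3:4, 3:4, 2] <- 1L
  expect_equal(dice3d(a, b), 0)
  # |A| = |B| = 4 with overlap 2 -> 0.5
  c1 <- array(0L, c(4, 4, 1)); c1[1:4, 1, 1] <- 1L
  c2 <- array(0L, c(4, 4, 1)); c2[3:4, 1, 1] <- 1L; c2[1:2, 2, 1] <- 1L
  expect_equal(dice3d(c1, c2), 0.5)
  expect_equal(dice3d(a, b), dice3d(b, a))
  z <- array(0L, c(3, 3, 3))
  expect_equal(dice3d(z, z), 1)
  expect_error(dice3d(a, z), "shape")
})

test_that("MTV and TLG follow their closed forms", {
  m <- array(0L, c(10, 10, 4)); m[1:100] <- 1L # 100 voxels
  expect_equal(mtv(m, c(2, 2, 3)), 1.2) # 100 x 12 mm^3 = 1.2 ml
  expect_equal(mtv(array(0L, c(4, 4, 4)), c(2, 2, 3)), 0)
  withr::with_seed(6, {
    r <- array(rbinom(200, 1, 0.3), c(10, 10, 2))
    expect_equal(mtv(r, c(1.5, 1.5, 2)), sum(r) * 4.5 / 1000)
  })
  # two 12 mm^3 voxels at SUV 2 and 4: mean 3 x 0.024 ml = 0.072 g
  mk <- array(0L, c(2, 2, 1)); mk[1:2, 1, 1] <- 1L
  suv <- array(0, c(2, 2, 1)); suv[1, 1, 1] <- 2; suv[2, 1, 1] <- 4
  expect_equal(tlg(mk, suv, c(2, 2, 3)), 0.072)
  expect_equal(tlg(mk * 0L, suv, c(2, 2, 3)), 0)
  # uniform SUV u over volume V gives exactly u * V
  u <- array(0L, c(6, 6, 6)); u[2:4, 2:4, 2:4] <- 1L
  su <- array(5.5, c(6, 6, 6))
  expect_equal(tlg(u, su, c(2, 2, 2)), 5.5 * mtv(u, c(2, 2, 2)))
  expect_error(tlg(u, array(1, c(2, 2, 2)), c(2, 2, 2)), "shape")
})

test_that("ICC(2,1) matches an aov-based mean-squares oracle", {
  icc_oracle <- function(x, y) {
    n <- length(x)
    df <- data.frame(score = c(x, y),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(score ~ subject + rater, data = df))[[1]]$`Mean Sq`
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  }
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- sample(5:40, 1)
      x <- stats::rnorm(n, sd = stats::runif(1, 0.5, 5))
      y <- 0.5 * x + stats::rnorm(n, mean = stats::runif(1, -2, 2))
      ic <- icc_agreement(x, y)
      expect_equal(ic$icc, icc_oracle(x, y), tolerance = 1e-10)
      expect_gte(ic$icc, -1); expect_lte(ic$icc, 1)
      expect_lte(ic$ci_low, ic$icc); expect_gte(ic$ci_high, ic$icc)
      # invariant under exchanging the raters
      expect_equal(icc_agreement(y, x)$icc, ic$icc, tolerance = 1e-12)
    }
  })
  x <- c(1, 2, 3, 4, 5, 6.5)
  expect_equal(icc_agreement(x, x)$icc, 1)
  # absolute agreement penalizes offsets that Pearson ignores
  y <- x + 10
  expect_lt(icc_agreement(x, y)$icc, stats::cor(x, y))
  expect_error(icc_agreement(1:4, 1:4), "at least 5")
  expect_error(icc_agreement(rep(1, 6), rep(1, 6)), "zero variance")
})

test_that("median/IQR summaries use interpolated quartiles", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)), tibble::tibble(median = 3, iqr = 2))
  expect_equal(median_iqr(7), tibble::tibble(median = 7, iqr = 0))
  withr::with_seed(8, {
    x <- stats::rnorm(37)
    s <- sort(x)
    q <- function(p) { # type-7 quantile from sorted order statistics
      h <- (37 - 1) * p; lo <- floor(h)
      if (lo >= 36) s[37] else s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
    }
    mi <- median_iqr(x)
    expect_equal(mi$median, stats::median(x))
    expect_equal(mi$iqr, q(0.75) - q(0.25), tolerance = 1e-12)
  })
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("biomarker reports keep the TLG = meanSUV x MTV invariant", {
  v <- generate_volume(toy_cohort()$config, 55L)
  rep <- biomarker_report(v$gt_mask, v$pet_suv, v$voxel_spacing,
                          gt_mask = v$gt_mask, subject_id = "s")
  expect_equal(rep$tlg_g, rep$suv_mean * rep$mtv_ml, tolerance = 1e-9)
  expect_equal(rep$dice, 1)
  expect_equal(rep$mtv_dev, 0)
  expect_gte(rep$mtv_ml, 0)
})
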