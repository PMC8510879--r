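test_that("volume generation is deterministic and internally consistent", {
  cfg <- toy_cohort()$config
  v1 <- generate_volume(cfg, 99L)
  v2 <- generate_volume(cfg, 99L)
  expect_identical(v1, v2)
  expect_true(all(v1$pet_suv >= 0))
  expect_identical(dim(v1$pet_suv), dim(v1$ct_hu))
  expect_identical(dim(v1$pet_suv), dim(v1$gt_mask))
  # slice labels match the mask exhaustively, for several subjects
  for (s in c(1L, 5L, 17L)) {
    v <- generate_volume(cfg, s)
    expect_identical(v$slice_labels, derive_slice_labels(v$gt_mask))
  }
})

test_that("a zero positive-slice fraction yields tumor-free volumes", {
  cfg <- phantom_config(n_subjects = 5L, slices_per_subject = 8L,
                        slice_shape = c(32L, 32L),
                        positive_slice_fraction = 0,
                        physiological_hotspot_rate = 0, seed = 1L)
  v <- generate_volume(cfg, 3L)
  expect_true(all(v$gt_mask == 0))
  expect_true(all(v$slice_labels == 0))
})

test_that("lesion sizes are right-skewed, against a direct moment oracle", {
  cfg <- phantom_config(lesion_size_meanlog = 3.0, lesion_size_sdlog = 0.8)
  sizes <- withr::with_seed(5L, sample_lesion_sizes(10000L, cfg))
  expect_gt(moment_skewness(sizes), 0)
  expect_true(all(sizes >= 1))
})

test_that("subject-level split is an exact 60/20/20 partition", {
  cfg <- phantom_config(n_subjects = 10L, slices_per_subject = 4L,
                        slice_shape = c(16L, 16L), seed = 2L)
  co <- generate_cohort(cfg)
  expect_equal(unname(table(co$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)
  expect_identical(sort(co$subject_id), sort(unique(co$subject_id)))
  by_split <- split(co$subject_id, co$split)
  expect_length(Reduce(intersect, by_split), 0L)
  expect_setequal(unlist(by_split), co$subject_id)
})

test_that("the cohort hits the configured positive-slice fraction", {
  # 100 subjects x 64 slices at the clinical 13.5% target
  cfg <- phantom_config(n_subjects = 100L, slices_per_subject = 64L,
                        slice_shape = c(32L, 32L),
                        positive_slice_fraction = 0.135, seed = 31L)
  labs <- unlist(lapply(seq_len(cfg$n_subjects), function(i)
    generate_volume(cfg, cfg$seed * 1000L + i)$slice_labels))
  frac <- mean(labs)
  expect_gte(frac, 0.105)
  expect_lte(frac, 0.165)
})

test_that("lesion SUV stochastically dominates background SUV", {
  cfg <- toy_cohort()$config
  v <- generate_volume(cfg, 12L)
  lesion <- v$pet_suv[v$gt_mask == 1]
  body <- v$ct_hu > -200 & v$gt_mask == 0
  background <- v$pet_suv[body]
  expect_gt(length(lesion), 0)
  wt <- stats::wilcox.test(lesion, background, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(positive_slice_fraction = 1.2), "fraction")
  expect_error(phantom_config(voxel_spacing = c(2, 0, 3)), "spacing")
  expect_error(phantom_config(n_subjects = 0), "counts")
  expect_error(phantom_config(lesion_suv = c(1, 0.1), background_suv = c(2, 0.1)),
               "exceed")
  expect_error(generate_cohort(phantom_config(n_subjects = 4L)), "n_subjects >= 5")
})
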