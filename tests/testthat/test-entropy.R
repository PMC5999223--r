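test_that("level distributions are empirical relative frequencies", {
  d <- level_distribution(c(2, 2, 2))
  expect_equal(unname(d$probs), 1)
  expect_equal(d$m, 3)
  d <- level_distribution(c(0, 1, 1, 6))
  expect_equal(d$probs, c(`0` = 0.25, `1` = 0.5, `6` = 0.25))
  set.seed(5)
  for (i in 1:20)
    expect_equal(sum(level_distribution(sample(0:4, 7, TRUE))$probs), 1)
  expect_error(level_distribution(integer(0)), "empty")
})

test_that("point-sum entropy matches hand evaluations and the literal oracle", {
  expect_identical(entropy_pointsum(rep(2, 6)), 0)
  # two levels, three points each: six terms of -(1/2)log2(1/2)
  expect_equal(entropy_pointsum(c(1, 1, 1, 4, 4, 4)), 3)
  # six all-distinct levels: six terms of -(1/6)log2(1/6)
  expect_equal(entropy_pointsum(0:5), log2(6))
  set.seed(7)
  for (i in 1:200) {
    lv <- sample(0:4, sample(1:10, 1), replace = TRUE)
    expect_equal(entropy_pointsum(lv), oracle_pointsum(lv), tolerance = 1e-12)
  }
})

test_that("entropy is invariant to point order and level relabeling", {
  set.seed(13)
  for (i in 1:50) {
    lv <- sample(0:9, 12, replace = TRUE)
    perm <- sample(lv)
    relab <- match(lv, sample(0:9)) - 1L  # injective relabeling
    expect_equal(entropy_pointsum(perm), entropy_pointsum(lv))
    expect_equal(entropy_pointsum(relab), entropy_pointsum(lv))
    expect_equal(entropy_shannon(perm), entropy_shannon(lv))
  }
})

test_that("entropy is zero exactly when all points share one level", {
  set.seed(17)
  for (i in 1:100) {
    lv <- sample(0:4, sample(2:9, 1), replace = TRUE)
    if (length(unique(lv)) == 1) {
      expect_identical(entropy_pointsum(lv), 0)
      expect_identical(entropy_shannon(lv), 0)
    } else {
      expect_gt(entropy_pointsum(lv), 0)
      expect_gt(entropy_shannon(lv), 0)
    }
  }
})

test_that("Shannon entropy respects its log2(min(m, L)) bound", {
  expect_equal(entropy_shannon(c(1, 1, 1, 4, 4, 4)), 1)
  set.seed(19)
  for (i in 1:100) {
    m <- sample(1:12, 1)
    lv <- sample(0:9, m, replace = TRUE)
    expect_lte(entropy_shannon(lv), log2(min(m, 10)) + 1e-12)
    expect_gte(entropy_shannon(lv), 0)
  }
})

test_that("maximum entropy follows the m/L closed form", {
  expect_equal(round(entropy_max(6, 5), 3), 2.786)
  expect_equal(round(entropy_max(6, 10), 3), 1.993)
  expect_equal(entropy_max(4, 1), 0)
  expect_equal(entropy_max(6, 5), 6 * (1 / 5) * log2(5))
  # vectorized
  expect_equal(entropy_max(c(6, 6), c(5, 10)),
               c(entropy_max(6, 5), entropy_max(6, 10)))
})

test_that("per-point entropy per point approaches 1/L log2 L for uniform levels", {
  set.seed(23)
  lv <- sample(0:9, 600, replace = TRUE)
  expect_equal(entropy_pointsum(lv) / 600, entropy_max(1, 10),
               tolerance = 0.02)
})

test_that("rarefied entropy matches subsampling and removes depth", {
  lv <- c(0, 0, 0, 1, 1, 2)
  # full depth: identical to the plug-in estimate
  expect_equal(entropy_rarefied(lv, 6), entropy_shannon(lv))
  expect_equal(entropy_rarefied(lv, 1), 0)
  # Monte-Carlo subsampling oracle at depth 3
  set.seed(29)
  mc <- mean(replicate(20000, entropy_shannon(sample(lv, 3))))
  expect_equal(entropy_rarefied(lv, 3), mc, tolerance = 0.01)
  expect_error(entropy_rarefied(lv, 7), "depth")
})

test_that("profiles cover every case and flag absent features as missing", {
  sim <- simulate_cohort(null_config(12, seed = 31))
  prof <- compute_entropy_profiles(sim$slides)
  expect_equal(nrow(prof), 12 * 4)
  expect_false(anyNA(prof$H_point))

  # homogeneous cohort: every entropy 0
  sim0 <- simulate_cohort(null_config(8, seed = 37, alpha = 1e-9))
  prof0 <- compute_entropy_profiles(sim0$slides)
  expect_true(all(prof0$H_point == 0))

  # drop one case's CD23 slides entirely: its CD23 features go NA, not 0
  ct <- sim$slides
  victim <- ct$slides$case_id[1]
  keep <- !(ct$slides$case_id == victim & ct$slides$staining == "CD23")
  ct2 <- case_table(ct$slides[keep, ], ct$specs)
  w <- capture_warnings(prof2 <- compute_entropy_profiles(ct2))
  expect_true(any(grepl(victim, w)))
  got <- prof2[prof2$case_id == victim & prof2$variable == "n_follicle", ]
  expect_true(is.na(got$H_point))
  expect_equal(nrow(prof2), 12 * 4)
})

test_that("entropy tables pivot wide and round-trip to CSV", {
  prof <- compute_entropy_profiles(demo_slide_table())
  w <- profiles_wide(prof)
  expect_equal(w$H_point_n_follicle[w$case_id == "DEMO_HET"], log2(6))
  path <- tempfile(fileext = ".csv")
  write_entropy_table(prof, path)
  back <- read.csv(path)
  expect_equal(back$H_point_n_follicle, w$H_point_n_follicle)
  expect_equal(back$m_grading_atrophy, w$m_grading_atrophy)
})
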