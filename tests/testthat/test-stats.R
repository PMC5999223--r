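test_that("normality gate selects t for normal and wilcoxon for heavy tails", {
  set.seed(41)
  x <- rnorm(60); y <- rnorm(60)
  res <- gated_two_group_test(c(x, y), rep(c("f", "m"), each = 60))
  expect_equal(res$test_used, "t")
  expect_gt(res$p_value, 0.05)
  expect_true(all(res$shapiro_p > 0.05))

  xh <- rlnorm(60, sdlog = 1.5); yh <- rlnorm(60, sdlog = 1.5)
  res2 <- gated_two_group_test(c(xh, yh), rep(c("f", "m"), each = 60))
  expect_equal(res2$test_used, "wilcoxon")
})

test_that("constant group forces the rank-sum branch with a warning", {
  vals <- c(rep(1, 5), rnorm(5))
  expect_warning(res <- gated_two_group_test(vals, rep(c("a", "b"), each = 5)),
                 "constant")
  expect_equal(res$test_used, "wilcoxon")
  expect_error(gated_two_group_test(rnorm(9), rep(c("a", "b", "c"), 3)),
               "two groups")
  expect_error(gated_two_group_test(rnorm(4), c("a", "a", "b", "b")),
               "n >= 3")
})

test_that("Pearson correlation handles exact, null and degenerate input", {
  x <- 1:20
  res <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res$r, 1)
  set.seed(43)
  res2 <- pearson_with_p(rnorm(1000), rnorm(1000))
  expect_lt(abs(res2$r), 0.1)
  expect_equal(res2$n, 1000)
  expect_error(pearson_with_p(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_with_p(1:2, 1:2), "3 complete pairs")
})

test_that("model grid assigns families per endpoint layout and stars cells", {
  sim <- simulate_cohort(cohort_config(
    n_cases = 100, seed = 47,
    betas = list(prednisone_post_g = c(grading_intrathymic_fat = 3))))
  prof <- compute_entropy_profiles(sim$slides)
  grid <- fit_model_grid(prof, sim$clinical)
  expect_equal(unname(grid$family),
               c("logistic", "logistic", rep("linear", 4)))
  expect_equal(dim(grid$p_values), c(6, 5))
  expect_true(all(grid$p_values >= 0 & grid$p_values <= 1, na.rm = TRUE))
  expect_true(all(is.na(grid$r_squared[grid$family == "logistic"])))
  # the planted cell is overwhelmingly significant at this effect size
  expect_lt(grid$p_values["prednisone_post_g", "grading_intrathymic_fat"],
            0.05)
  sig <- significant_cells(grid)
  expect_true(any(sig$endpoint == "prednisone_post_g" &
                    sig$predictor == "grading_intrathymic_fat"))

  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_model_grid(grid, csv, js)
  tab <- read.csv(csv, check.names = FALSE)
  expect_equal(nrow(tab), 6)
  expect_match(tab[tab$endpoint == "prednisone_post_g",
                   "grading_intrathymic_fat"], "\\*")
  side <- jsonlite::read_json(js)
  expect_named(side$coefficients, default_endpoints()$endpoint)
})

test_that("degenerate endpoints error and separation is flagged, not fatal", {
  sim <- simulate_cohort(null_config(30, seed = 53))
  prof <- compute_entropy_profiles(sim$slides)
  cl <- sim$clinical
  cl$qmg_baseline <- 5
  expect_error(fit_model_grid(prof, cl), "zero variance")

  # perfect separation on an entropy predictor
  cl <- sim$clinical
  w <- profiles_wide(prof)
  cl$mms_m12_36 <- as.integer(w$H_point_n_follicle[
    match(cl$case_id, w$case_id)] > median(w$H_point_n_follicle))
  grid <- fit_model_grid(prof, cl)
  expect_false(grid$converged[["mms_m12_36"]])
})

test_that("single-predictor fits recover exact and planted slopes", {
  prof <- data.frame(case_id = sprintf("C%03d", 1:50),
                     variable = "grading_intrathymic_fat", staining = "HE",
                     m = 10L, H_point = seq(0, 5, length.out = 50),
                     H_shannon = seq(0, 2, length.out = 50), H_max = 3)
  cl <- data.frame(case_id = prof$case_id,
                   prednisone_post_g = 3 * prof$H_point)
  f <- suppressWarnings(fit_single_predictor(prof, cl, "prednisone_post_g",
                                             "grading_intrathymic_fat"))
  expect_equal(f$slope, 3)
  expect_equal(f$r_squared, 1)

  set.seed(59)
  cl$prednisone_post_g <- 10 + 5 * prof$H_point + rnorm(50)
  f2 <- fit_single_predictor(prof, cl, "prednisone_post_g",
                             "grading_intrathymic_fat")
  expect_lt(abs(f2$slope - 5), 3 * f2$std_error)

  cl$prednisone_post_g <- rnorm(50)
  f3 <- fit_single_predictor(prof, cl, "prednisone_post_g",
                             "grading_intrathymic_fat")
  expect_lt(f3$r_squared, 0.15)

  prof$H_point <- 1
  expect_error(fit_single_predictor(prof, cl, "prednisone_post_g",
                                    "grading_intrathymic_fat"),
               "constant predictor")
})

test_that("k-fold CV is seeded, near-balanced and near-zero on noiseless data", {
  prof <- data.frame(case_id = sprintf("C%03d", 1:31),
                     variable = "grading_intrathymic_fat", staining = "HE",
                     m = 10L, H_point = runif(31, 0, 5),
                     H_shannon = 0, H_max = 3)
  cl <- data.frame(case_id = prof$case_id,
                   prednisone_post_g = 1 + 2 * prof$H_point)
  cv <- kfold_cv(prof, cl, "prednisone_post_g",
                 predictors = "grading_intrathymic_fat", k = 3, seed = 61)
  expect_equal(cv$k, 3)
  expect_lte(diff(range(cv$fold_sizes)), 1)
  expect_true(all(cv$fold_mse < 1e-20))

  cv2 <- kfold_cv(prof, cl, "prednisone_post_g",
                  predictors = "grading_intrathymic_fat", k = 3, seed = 61)
  expect_identical(cv, cv2)
  cv3 <- kfold_cv(prof, cl, "prednisone_post_g",
                  predictors = "grading_intrathymic_fat", k = 3, seed = 62)
  expect_false(identical(cv$assignment, cv3$assignment))

  expect_error(kfold_cv(prof, cl, "prednisone_post_g",
                        predictors = "grading_intrathymic_fat", k = 16,
                        seed = 1),
               "n >= 2k")
})

test_that("sampling-depth diagnostic flags planted coupling and rejects constants", {
  # all cases share one m: correlation undefined
  df <- do.call(rbind, lapply(1:4, function(i) {
    d <- tiny_slide_table()
    d$case_id <- sprintf("CASE%02d", i)
    d$slide_id <- sprintf("%s_B%02d_HE", d$case_id, 1:3)
    d$grading_atrophy <- c(i %% 4, 2, 3)
    d
  }))
  expect_error(entropy_sample_size_check(case_table(df), "grading_atrophy"),
               "constant")

  # heterogeneity planted to grow with slide count
  sim <- simulate_cohort(null_config(150, seed = 67, alpha_m_coupling = 3))
  chk <- entropy_sample_size_check(sim$slides)
  expect_gt(chk$r, 0.3)
  expect_lt(chk$p_value, 0.01)
  expect_equal(attr(chk, "estimator"), "rarefied")

  # the m-scaled point-sum estimator is structurally coupled to m
  chk_pt <- entropy_sample_size_check(
    simulate_cohort(null_config(150, seed = 71))$slides, estimator = "point")
  expect_gt(chk_pt$r, 0.2)
})
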