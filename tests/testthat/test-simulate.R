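test_that("cohort config validates its inputs", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(alpha = -1, seed = 1), "positive")
  expect_error(cohort_config(betas = list(nonsense = c(n_follicle = 1)),
                             seed = 1), "unknown endpoint")
  expect_error(cohort_config(betas = list(qmg_baseline = c(bogus = 1)),
                             seed = 1), "unknown feature")
})

test_that("same config regenerates the cohort bit-identically", {
  cfg <- cohort_config(n_cases = 15, seed = 73)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$slides$slides, b$slides$slides)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$manifest$cases, b$manifest$cases)
  # and the files written are byte-identical
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in c("slides.csv", "clinical.csv", "manifest.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("generated tables respect the package schemas", {
  sim <- simulate_cohort(cohort_config(n_cases = 20, seed = 79))
  d <- file.path(tempdir(), "cohC")
  write_cohort(sim, d)
  ct <- read_slide_table(file.path(d, "slides.csv"))
  expect_equal(n_cases(ct), 20)
  expect_identical(attr(ct, "row_errors")$row, integer(0))
  cl <- read_clinical_table(file.path(d, "clinical.csv"))
  expect_equal(nrow(cl), 20)
  expect_true(all(cl$qmg_drop_m12_36 %in% 0:1))
  # block counts: floored at 3, two stain rows per block
  nb <- table(ct$slides$case_id) / 2
  expect_true(all(nb >= 3))
  expect_equal(unname(nb[sim$manifest$cases$case_id]),
               unname(as.table(sim$manifest$cases$n_blocks)),
               ignore_attr = TRUE)
})

test_that("near-zero concentration collapses every case to zero entropy", {
  sim <- simulate_cohort(null_config(10, seed = 83, alpha = 1e-9))
  prof <- compute_entropy_profiles(sim$slides)
  expect_true(all(prof$H_point == 0))
  expect_true(all(prof$H_shannon == 0))
})

test_that("mean realized entropy is non-decreasing in the concentration", {
  means <- vapply(c(0.05, 0.5, 5, 50), function(a) {
    sim <- simulate_cohort(null_config(200, seed = 89, alpha = a))
    mean(sim$manifest$cases$shannon_n_follicle)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("pipeline-estimated entropies agree with the manifest truth", {
  sim <- simulate_cohort(null_config(60, seed = 97))
  w <- profiles_wide(compute_entropy_profiles(sim$slides))
  truth <- sim$manifest$cases
  expect_equal(w$H_point_n_follicle[match(truth$case_id, w$case_id)],
               truth$n_follicle)
  keep <- truth$n_blocks >= 10
  expect_gt(cor(w$H_point_grading_atrophy[match(truth$case_id,
                                                w$case_id)][keep],
                truth$grading_atrophy[keep]), 0.95)
})

test_that("null cohorts show no endpoint-entropy correlation on average", {
  cors <- vapply(1:20, function(i) {
    sim <- simulate_cohort(null_config(55, seed = 100 + i))
    cor(sim$clinical$prednisone_post_g,
        sim$manifest$cases$grading_intrathymic_fat)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("demo slide table exercises the level boundaries as designed", {
  ct <- demo_slide_table()
  path <- tempfile(fileext = ".csv")
  write_slide_table(ct, path)
  back <- read_slide_table(path)
  expect_equal(n_cases(back), 2)
  expect_identical(attr(back, "row_errors")$row, integer(0))

  prof <- compute_entropy_profiles(back)
  hom <- prof[prof$case_id == "DEMO_HOM", ]
  expect_true(all(hom$H_point == 0))
  het <- prof[prof$case_id == "DEMO_HET", ]
  expect_equal(het$H_point[het$variable == "n_follicle"], log2(6))
  # boundary values present: <5, =5, =50 follicles; grades 0 and 4
  nf <- ct$slides$n_follicle[!is.na(ct$slides$n_follicle)]
  expect_true(any(nf < 5) && any(nf == 5) && any(nf == 50))
  expect_setequal(range(ct$slides$grading_atrophy, na.rm = TRUE), c(0, 4))
})
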