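# shared fixtures and independent oracles, built in code

# literal per-point evaluation of the point-sum entropy: one term per
# measurement point, each -p_i * log2(p_i) with p_i the relative frequency
# of that point's level (independent of the package implementation)
oracle_pointsum <- function(levels) {
  h <- 0
  for (i in seq_along(levels)) {
    p <- mean(levels == levels[i])
    h <- h - p * log2(p)
  }
  h
}

# minimal 3-slide, single-case slide table
tiny_slide_table <- function() {
  data.frame(
    case_id = "CASE01",
    region = c("A", "RU", "LL"),
    slide_id = c("CASE01_B01_HE", "CASE01_B02_HE", "CASE01_B03_HE"),
    staining = "HE",
    grading_atrophy = c(2, 2, 3),
    grading_intrathymic_fat = c(10, 55, 80),
    n_follicle = c(2, 7, 31),
    stringsAsFactors = FALSE
  )
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

# cohort config with no planted effects
null_config <- function(n_cases, seed, ...) {
  cohort_config(n_cases = n_cases, betas = list(), seed = seed, ...)
}
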