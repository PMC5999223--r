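#' Construct a case table from a slide-level data.frame
#'
#' A `case_table` bundles validated slide-level measurements with the variable
#' registry they were validated against. Rows are slides; `case_id` groups
#' slides into cases; each slide contributes one measurement point per
#' variable it carries a non-missing value for.
#'
#' @param slides data.frame with columns `case_id`, `region`, `slide_id`,
#'   `staining` and one column per measured variable.
#' @param specs variable registry as returned by [histo_variables()].
#' @return An object of class `case_table`.
#' @export
case_table <- function(slides, specs = histo_variables()) {
  req <- c("case_id", "region", "slide_id", "staining")
  miss <- setdiff(req, names(slides))
  if (length(miss) > 0)
    stop("slide table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(slides$slide_id))
    stop("duplicate slide_id: ",
         paste(unique(slides$slide_id[duplicated(slides$slide_id)]),
               collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(slides$staining), staining_codes())
  if (length(bad) > 0)
    stop("unknown staining code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(slides = slides, specs = specs), class = "case_table")
}

#' @export
print.case_table <- function(x, ...) {
  vars <- intersect(x$specs$variable, names(x$slides))
  cat("case_table:", length(unique(x$slides$case_id)), "cases,",
      nrow(x$slides), "slides,", length(vars), "variables\n")
  invisible(x)
}

#' Number of cases in a case table
#' @param x a `case_table`.
#' @return integer case count.
#' @export
n_cases <- function(x) length(unique(x$slides$case_id))

#' Read a slide-level measurement table
#'
#' Reads delimited text with one row per slide, validates it against the
#' variable registry, and returns a [case_table()]. Rows whose numeric values
#' fall outside a variable's declared range are rejected with a row-level
#' diagnostic naming the row, variable and offending value; missing cells are
#' preserved as `NA`. Unknown extra columns are carried through untouched.
#'
#' @param path file path.
#' @param specs variable registry, default [histo_variables()].
#' @param sep field separator: `","` (default), `"\t"` or `";"`.
#' @param region_vocab allowed region codes; `NULL` disables the check.
#' @return A `case_table`. Rejected-row diagnostics, if any, are attached as
#'   attribute `"row_errors"` (a data.frame with `row`, `variable`, `message`)
#'   and summarised in a warning.
#' @export
read_slide_table <- function(path, specs = histo_variables(), sep = ",",
                             region_vocab = region_codes()) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  req <- c("case_id", "region", "slide_id", "staining")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("slide table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  numeric_vars <- intersect(specs$variable[specs$scale != "nominal"],
                            names(raw))
  errors <- data.frame(row = integer(), variable = character(),
                       message = character(), stringsAsFactors = FALSE)
  reject <- rep(FALSE, nrow(raw))
  for (v in numeric_vars) {
    spec <- specs[specs$variable == v, ]
    txt <- raw[[v]]
    val <- suppressWarnings(as.numeric(txt))
    bad_parse <- !is.na(txt) & nzchar(trimws(txt)) & is.na(val)
    out_of_range <- !is.na(val) & (val < spec$range_min | val > spec$range_max)
    for (i in which(bad_parse))
      errors <- rbind(errors, data.frame(
        row = i, variable = v,
        message = sprintf("unparseable value '%s'", txt[i])))
    for (i in which(out_of_range))
      errors <- rbind(errors, data.frame(
        row = i, variable = v,
        message = sprintf("value %g outside range [%g, %g]",
                          val[i], spec$range_min, spec$range_max)))
    reject <- reject | bad_parse | out_of_range
    raw[[v]] <- val
  }
  if (!is.null(region_vocab)) {
    bad_region <- !(raw$region %in% region_vocab)
    for (i in which(bad_region))
      errors <- rbind(errors, data.frame(
        row = i, variable = "region",
        message = sprintf("unknown region code '%s'", raw$region[i])))
    reject <- reject | bad_region
  }
  if (any(reject))
    warning(sum(reject), " row(s) rejected (see attr(, 'row_errors')): e.g. ",
            errors$message[1], " [row ", errors$row[1], ", ",
            errors$variable[1], "]", call. = FALSE)
  ct <- case_table(raw[!reject, , drop = FALSE], specs)
  attr(ct, "row_errors") <- errors
  ct
}

#' Write a slide table to delimited text
#' @param ct a `case_table`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_slide_table <- function(ct, path, sep = ",") {
  utils::write.table(ct$slides, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read the per-case clinical covariate table
#'
#' One row per case: demographics (age, sex, BMI), disease severity and
#' duration, the two binary clinical endpoints (3-point QMG drop and minimal
#' manifestation status between months 12 and 36), and the pre-/post-operative
#' prednisone loads (area under the dose-time curve, grams).
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame keyed by `case_id`.
#' @export
read_clinical_table <- function(path, sep = ",") {
  cl <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  if (!"case_id" %in% names(cl))
    stop("clinical table is missing case_id", call. = FALSE)
  cl$case_id <- as.character(cl$case_id)
  dup <- unique(cl$case_id[duplicated(cl$case_id)])
  if (length(dup) > 0)
    stop("duplicate case_id in clinical table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  for (ep in intersect(c("qmg_drop_m12_36", "mms_m12_36"), names(cl))) {
    ok <- is.na(cl[[ep]]) | cl[[ep]] %in% c(0, 1)
    if (!all(ok))
      stop("non-binary value in endpoint ", ep, " (rows ",
           paste(which(!ok), collapse = ", "), ")", call. = FALSE)
  }
  for (dose in intersect(c("prednisone_pre_g", "prednisone_post_g"), names(cl))) {
    neg <- !is.na(cl[[dose]]) & cl[[dose]] < 0
    if (any(neg))
      stop("negative dose in ", dose, " (rows ",
           paste(which(neg), collapse = ", "), ")", call. = FALSE)
  }
  cl
}

#' Write the clinical table to delimited text
#' @param clinical data.frame as returned by [read_clinical_table()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_clinical_table <- function(clinical, path, sep = ",") {
  utils::write.table(clinical, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

# slide rows contributing measurement points for a variable/staining
contributing_slides <- function(ct, variable, staining = NULL) {
  if (!variable %in% names(ct$slides))
    stop("variable not present in slide table: ", variable, call. = FALSE)
  s <- ct$slides
  if (!is.null(staining)) s <- s[s$staining %in% staining, , drop = FALSE]
  s[!is.na(s[[variable]]), , drop = FALSE]
}

#' Measurement points per case
#'
#' Counts, per case, the slides carrying a non-missing value of `variable`
#' (optionally restricted to a staining) — the per-case m that entropy is
#' defined over.
#'
#' @param ct a `case_table`.
#' @param variable variable name.
#' @param staining optional staining filter (character vector).
#' @return named integer vector, one entry per case present in `ct` (cases
#'   with no contributing slide report 0).
#' @export
m_points <- function(ct, variable, staining = NULL) {
  s <- contributing_slides(ct, variable, staining)
  ids <- sort(unique(ct$slides$case_id))
  m <- table(factor(s$case_id, levels = ids))
  stats::setNames(as.integer(m), ids)
}

#' Per-case location summaries of a slide-level variable
#'
#' Computes, over the non-missing slide values of each case, the classic
#' location parameters: mean, median, mode (most frequent value, smallest on
#' ties) and min-max range. Cases whose values are all missing are retained
#' with `NA` summaries.
#'
#' @param ct a `case_table`.
#' @param variable an ordinal or interval variable name.
#' @param staining optional staining filter.
#' @return data.frame with columns `case_id`, `n`, `mean`, `median`, `mode`,
#'   `min`, `max`.
#' @export
summarize_per_case <- function(ct, variable, staining = NULL) {
  spec <- ct$specs[ct$specs$variable == variable, ]
  if (nrow(spec) == 1 && spec$scale == "nominal")
    stop("unsupported scale: ", variable, " is nominal", call. = FALSE)
  s <- ct$slides
  if (!is.null(staining)) s <- s[s$staining %in% staining, , drop = FALSE]
  ids <- sort(unique(ct$slides$case_id))
  out <- lapply(ids, function(id) {
    x <- s[[variable]][s$case_id == id]
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(data.frame(case_id = id, n = 0L, mean = NA_real_,
                        median = NA_real_, mode = NA_real_,
                        min = NA_real_, max = NA_real_))
    tab <- table(x)
    data.frame(case_id = id, n = length(x), mean = mean(x),
               median = stats::median(x),
               mode = as.numeric(names(tab)[which.max(tab)]),
               min = min(x), max = max(x))
  })
  do.call(rbind, out)
}
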