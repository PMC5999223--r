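#' Define a level scheme for one variable
#'
#' A level scheme maps raw slide-level values to integer levels `0..L-1`, the
#' alphabet over which per-case entropy is computed. Interval variables use
#' left-closed, right-open bins given by `edges`; ordinal grades use the
#' identity mapping. The top range value is clamped into the last bin so that
#' e.g. 50 follicles or 100% fat are valid inputs.
#'
#' @param variable variable name.
#' @param edges strictly increasing numeric bin boundaries of length `L + 1`
#'   tiling the variable's range (interval schemes), or `NULL` for ordinal.
#' @param ordinal logical; identity scheme on integer grades.
#' @param range numeric length-2 admissible raw range; for ordinal schemes
#'   levels are `range[1]..range[2]` shifted to start at 0.
#' @param clamp_above optional upper bound above `max(edges)` up to which raw
#'   values are accepted and clamped into the top level with a warning (used
#'   for follicle counts, whose recorded range exceeds the binning range).
#' @return An object of class `level_scheme` with element `n_levels`.
#' @export
level_scheme <- function(variable, edges = NULL, ordinal = FALSE,
                         range = NULL, clamp_above = NULL) {
  if (ordinal) {
    if (is.null(range)) stop("ordinal scheme needs a range", call. = FALSE)
    n_levels <- as.integer(range[2] - range[1] + 1)
  } else {
    if (is.null(edges) || length(edges) < 2 || any(diff(edges) <= 0))
      stop("interval scheme needs strictly increasing edges", call. = FALSE)
    if (is.null(range)) range <- range(edges)
    if (!isTRUE(all.equal(c(edges[1], edges[length(edges)]), range)) &&
        is.null(clamp_above))
      stop("edges must tile the declared range", call. = FALSE)
    n_levels <- length(edges) - 1L
  }
  structure(list(variable = variable, edges = edges, ordinal = ordinal,
                 range = range, n_levels = n_levels,
                 clamp_above = clamp_above),
            class = "level_scheme")
}

#' @export
print.level_scheme <- function(x, ...) {
  cat("level_scheme:", x$variable, "-", x$n_levels, "levels",
      if (x$ordinal) "(ordinal identity)" else
        paste0("edges [", paste(x$edges, collapse = ", "), ")"), "\n")
  invisible(x)
}

#' Default level schemes
#'
#' The a priori discretization used throughout: ordinal gradings (atrophy,
#' follicular hyperplasia) keep their 5 grades 0-4 as identity levels; follicle
#' counts are binned into 10 levels of width 5 over 0-50 (level 0 = fewer than
#' 5 follicles, level 1 = 5 to fewer than 10, ...), with counts above 50
#' clamped into the top level; percentage variables (overall fat, intrathymic
#' fat, B-cell infiltrate area) get 10 levels of width 10% over 0-100%. Bin
#' counts are fixed a priori — coarse enough that neighbouring estimates (5%
#' vs 8% fat) share a level, fine enough not to flatten real heterogeneity.
#'
#' @return Named list of [level_scheme()] objects.
#' @export
#' @examples
#' default_schemes()$grading_atrophy$n_levels  # 5
#' default_schemes()$n_follicle$n_levels       # 10
default_schemes <- function() {
  pct <- function(v) level_scheme(v, edges = seq(0, 100, by = 10))
  counts <- function(v) level_scheme(v, edges = seq(0, 50, by = 5),
                                     clamp_above = 100)
  list(
    grading_atrophy = level_scheme("grading_atrophy", ordinal = TRUE,
                                   range = c(0, 4)),
    grading_follicle = level_scheme("grading_follicle", ordinal = TRUE,
                                    range = c(0, 4)),
    n_follicle = counts("n_follicle"),
    n_follicle_gc = counts("n_follicle_gc"),
    n_follicle_no_gc = counts("n_follicle_no_gc"),
    grading_overall_fat = pct("grading_overall_fat"),
    grading_intrathymic_fat = pct("grading_intrathymic_fat"),
    area_b_cell_infiltrate = pct("area_b_cell_infiltrate")
  )
}

#' Map raw values to integer levels
#'
#' Left-closed, right-open binning: a value in `[edges[k], edges[k+1])` gets
#' level `k - 1` (0-based). The top range value falls into the last level.
#' Ordinal schemes return the grade itself (shifted to 0 if the grade range
#' does not start at 0). Values outside the admissible range raise an error
#' naming the variable and value; values between the top edge and
#' `clamp_above` are clamped into the top level with a warning.
#'
#' @param value numeric vector of raw values (no `NA`).
#' @param scheme a [level_scheme()].
#' @return integer vector of levels in `0..n_levels-1`.
#' @export
#' @examples
#' sch <- default_schemes()$n_follicle
#' assign_level(c(3, 5, 50), sch)  # 0, 1, 9
assign_level <- function(value, scheme) {
  if (anyNA(value)) stop("assign_level: NA value", call. = FALSE)
  if (scheme$ordinal) {
    out_of <- value < scheme$range[1] | value > scheme$range[2]
    if (any(out_of))
      stop(sprintf("value %g outside range [%g, %g] for %s",
                   value[which(out_of)[1]], scheme$range[1], scheme$range[2],
                   scheme$variable), call. = FALSE)
    return(as.integer(value - scheme$range[1]))
  }
  lo <- scheme$edges[1]
  hi <- scheme$edges[length(scheme$edges)]
  top <- if (is.null(scheme$clamp_above)) hi else scheme$clamp_above
  out_of <- value < lo | value > top
  if (any(out_of))
    stop(sprintf("value %g outside range [%g, %g] for %s",
                 value[which(out_of)[1]], lo, top, scheme$variable),
         call. = FALSE)
  clamped <- value > hi
  if (any(clamped)) {
    warning(sum(clamped), " value(s) of ", scheme$variable, " above ", hi,
            " clamped into the top level", call. = FALSE)
    value[clamped] <- hi
  }
  lev <- findInterval(value, scheme$edges, rightmost.closed = TRUE) - 1L
  as.integer(lev)
}

#' Discretize one variable of a case table into per-case level sequences
#'
#' Applies a level scheme to the non-missing slide values of `variable`
#' (optionally restricted to a staining), per case. Slides are ordered by
#' `slide_id` so the sequence is deterministic; its length is the case's
#' number of measurement points m. Cases with zero contributing slides are
#' skipped with a warning.
#'
#' @param ct a `case_table`.
#' @param variable variable name.
#' @param scheme a [level_scheme()]; defaults to the variable's entry in
#'   [default_schemes()].
#' @param staining optional staining filter.
#' @return Named list (by `case_id`) of integer level vectors, with the
#'   scheme's `n_levels` attached as attribute `"n_levels"`.
#' @export
discretize_case <- function(ct, variable, scheme = NULL, staining = NULL) {
  if (is.null(scheme)) {
    scheme <- default_schemes()[[variable]]
    if (is.null(scheme))
      stop("no default level scheme for ", variable, call. = FALSE)
  }
  s <- contributing_slides(ct, variable, staining)
  s <- s[order(s$slide_id), , drop = FALSE]
  ids <- sort(unique(ct$slides$case_id))
  by_case <- split(s[[variable]], factor(s$case_id, levels = ids))
  seqs <- lapply(by_case, function(x) {
    if (length(x) == 0) return(NULL)
    assign_level(x, scheme)
  })
  names(seqs) <- ids
  empty <- vapply(seqs, is.null, logical(1))
  if (any(empty))
    warning("no measurement points for ", variable, " in case(s): ",
            paste(ids[empty], collapse = ", "), " - skipped", call. = FALSE)
  seqs <- seqs[!empty]
  attr(seqs, "n_levels") <- scheme$n_levels
  seqs
}

#' Serialize level schemes to YAML
#' @param schemes named list of [level_scheme()] objects.
#' @param path output path.
#' @export
write_schemes <- function(schemes, path) {
  yaml::write_yaml(lapply(schemes, function(s) {
    out <- list(variable = s$variable)
    if (s$ordinal) {
      out$ordinal <- TRUE
      out$range <- s$range
    } else {
      out$edges <- s$edges
      if (!is.null(s$clamp_above)) out$clamp_above <- s$clamp_above
    }
    out
  }), path)
  invisible(path)
}

#' Read level schemes from YAML
#' @param path YAML file written by [write_schemes()].
#' @return named list of [level_scheme()] objects.
#' @export
read_schemes <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(s)
    level_scheme(s$variable, edges = s$edges,
                 ordinal = isTRUE(s$ordinal),
                 range = if (!is.null(s$range)) as.numeric(s$range),
                 clamp_above = s$clamp_above))
  stats::setNames(out, vapply(out, function(s) s$variable, character(1)))
}
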