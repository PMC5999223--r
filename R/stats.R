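#' Default clinical endpoints and their model families
#'
#' The six endpoints of the explorative model grid: the two binary outcomes
#' (3-point QMG drop and minimal manifestation status, months 12-36) are fit
#' by logistic regression, the four linearly scaled ones (baseline QMG score,
#' disease duration, pre- and post-operative prednisone load) by linear
#' regression.
#'
#' @return data.frame with columns `endpoint`, `family`.
#' @export
default_endpoints <- function() {
  data.frame(
    endpoint = c("qmg_drop_m12_36", "mms_m12_36", "qmg_baseline",
                 "mg_duration_months", "prednisone_pre_g",
                 "prednisone_post_g"),
    family = c("logistic", "logistic", "linear", "linear", "linear",
               "linear"),
    stringsAsFactors = FALSE
  )
}

#' Normality-gated two-group comparison
#'
#' Tests each group for normality (Shapiro-Wilk at `alpha_gate`); if both
#' groups pass, a two-sided Welch t-test is used, otherwise a two-sided
#' Wilcoxon rank-sum test. A constant group cannot be gated and forces the
#' rank-sum test with a warning.
#'
#' @param values numeric vector.
#' @param groups vector with exactly two distinct values, same length.
#' @param alpha_gate significance level of the normality gate (default 0.05).
#' @return list of class `gated_test`: `test_used` (`"t"` or `"wilcoxon"`),
#'   `shapiro_p` (per group), `statistic`, `p_value`, `means`, `sds`, `n`.
#' @export
gated_two_group_test <- function(values, groups, alpha_gate = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  gl <- sort(unique(groups))
  if (length(gl) != 2)
    stop("need exactly two groups, got ", length(gl), call. = FALSE)
  split_v <- split(values, factor(groups, levels = gl))
  if (any(lengths(split_v) < 3))
    stop("each group needs n >= 3", call. = FALSE)
  shapiro_p <- vapply(split_v, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::shapiro.test(x)$p.value
  }, numeric(1))
  degenerate <- anyNA(shapiro_p)
  if (degenerate)
    warning("constant group values: normality gate forced to wilcoxon",
            call. = FALSE)
  use_t <- !degenerate && all(shapiro_p > alpha_gate)
  res <- if (use_t) stats::t.test(split_v[[1]], split_v[[2]])
         else suppressWarnings(stats::wilcox.test(split_v[[1]], split_v[[2]]))
  structure(list(
    test_used = if (use_t) "t" else "wilcoxon",
    shapiro_p = shapiro_p,
    statistic = unname(res$statistic),
    p_value = res$p.value,
    means = vapply(split_v, mean, numeric(1)),
    sds = vapply(split_v, stats::sd, numeric(1)),
    n = lengths(split_v)
  ), class = "gated_test")
}

#' @export
print.gated_test <- function(x, ...) {
  cat(sprintf("%s-test: statistic %.4g, p = %.4g (gate shapiro p: %s)\n",
              x$test_used, x$statistic, x$p_value,
              paste(signif(x$shapiro_p, 3), collapse = ", ")))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped);
#'   at least 3 complete pairs, both nonconstant.
#' @return list of class `correlation_result`: `r`, `p_value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.4g, n = %d\n", x$r, x$p_value, x$n))
  invisible(x)
}

merge_profiles_clinical <- function(profiles, clinical, predictors,
                                    estimator = c("point", "shannon")) {
  estimator <- match.arg(estimator)
  wide <- profiles_wide(profiles)
  pcols <- paste0("H_", estimator, "_", predictors)
  missing_cols <- setdiff(pcols, names(wide))
  if (length(missing_cols) > 0)
    stop("profiles lack predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d <- merge(wide[, c("case_id", pcols)], clinical, by = "case_id")
  names(d)[match(pcols, names(d))] <- predictors
  d
}

#' Explorative model grid: endpoints against the four entropy features
#'
#' For each clinical endpoint, fits one multivariable model of the endpoint on
#' all entropy predictors plus intercept — logistic regression for binary
#' endpoints, ordinary linear regression otherwise — and collects the
#' per-coefficient two-sided p-values (Wald z for logistic, t for linear).
#' Rows use listwise deletion. This grid is explorative: no multiple-testing
#' correction is applied, and significant cells are meant to be refit alone
#' ([fit_single_predictor()]).
#'
#' @param profiles long entropy profiles from [compute_entropy_profiles()].
#' @param clinical clinical table (see [read_clinical_table()]).
#' @param endpoints data.frame `endpoint`/`family`, default
#'   [default_endpoints()].
#' @param predictors entropy feature names, default the four of
#'   [default_entropy_features()].
#' @param estimator which entropy estimate enters the models: `"point"`
#'   (default) or `"shannon"`.
#' @param alpha significance threshold used for starring (default 0.05).
#' @return object of class `model_grid`: `p_values` (endpoint x coefficient
#'   matrix), `family`, `n`, `r_squared` (linear rows), `converged`,
#'   `coefficients` (per-endpoint coefficient tables), `alpha`, `estimator`.
#' @export
fit_model_grid <- function(profiles, clinical,
                           endpoints = default_endpoints(),
                           predictors = default_entropy_features()$variable,
                           estimator = c("point", "shannon"),
                           alpha = 0.05) {
  estimator <- match.arg(estimator)
  d <- merge_profiles_clinical(profiles, clinical, predictors, estimator)
  terms <- c("(Intercept)", predictors)
  p_values <- matrix(NA_real_, nrow(endpoints), length(terms),
                     dimnames = list(endpoints$endpoint, terms))
  r_squared <- stats::setNames(rep(NA_real_, nrow(endpoints)),
                               endpoints$endpoint)
  n_used <- converged <- stats::setNames(rep(NA, nrow(endpoints)),
                                         endpoints$endpoint)
  coefs <- list()
  fml <- stats::reformulate(predictors, response = NULL)
  for (i in seq_len(nrow(endpoints))) {
    ep <- endpoints$endpoint[i]
    if (!ep %in% names(d)) stop("endpoint not in clinical table: ", ep,
                                call. = FALSE)
    rows <- stats::complete.cases(d[, c(ep, predictors)])
    dd <- d[rows, , drop = FALSE]
    if (nrow(dd) < length(predictors) + 2)
      stop("too few complete cases for endpoint ", ep, call. = FALSE)
    if (stats::sd(dd[[ep]]) == 0)
      stop("endpoint has zero variance: ", ep, call. = FALSE)
    f <- stats::update(fml, paste(ep, "~ ."))
    ok <- TRUE
    fit <- if (endpoints$family[i] == "logistic") {
      withCallingHandlers(
        stats::glm(f, data = dd, family = stats::binomial()),
        warning = function(w) {
          ok <<- FALSE
          invokeRestart("muffleWarning")
        })
    } else {
      stats::lm(f, data = dd)
    }
    if (endpoints$family[i] == "logistic" && !fit$converged) ok <- FALSE
    sm <- summary(fit)
    tab <- sm$coefficients
    p_values[i, rownames(tab)] <- tab[, 4]
    if (endpoints$family[i] == "linear") r_squared[i] <- sm$r.squared
    n_used[i] <- nrow(dd)
    converged[i] <- ok
    coefs[[ep]] <- tab
  }
  structure(list(p_values = p_values, family = stats::setNames(
    endpoints$family, endpoints$endpoint),
    n = n_used, r_squared = r_squared, converged = converged,
    coefficients = coefs, alpha = alpha, estimator = estimator),
    class = "model_grid")
}

#' @export
print.model_grid <- function(x, ...) {
  disp <- matrix(sprintf("%.3f%s", x$p_values,
                         ifelse(x$p_values < x$alpha, " *", "")),
                 nrow(x$p_values), dimnames = dimnames(x$p_values))
  disp[is.na(x$p_values)] <- "-"
  cat("Explorative model grid (cells: p-values, * < ", x$alpha, "):\n",
      sep = "")
  print(cbind(as.data.frame(disp, check.names = FALSE),
              family = x$family), ...)
  flagged <- names(x$converged)[!is.na(x$converged) & !x$converged]
  if (length(flagged) > 0)
    cat("non-converged fit(s):", paste(flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Significant grid cells
#'
#' @param grid a `model_grid`.
#' @param alpha threshold, default the grid's own.
#' @return data.frame `endpoint`, `predictor`, `p_value` of entropy cells
#'   below `alpha` (intercepts excluded).
#' @export
significant_cells <- function(grid, alpha = grid$alpha) {
  p <- grid$p_values[, colnames(grid$p_values) != "(Intercept)", drop = FALSE]
  idx <- which(!is.na(p) & p < alpha, arr.ind = TRUE)
  data.frame(endpoint = rownames(p)[idx[, 1]],
             predictor = colnames(p)[idx[, 2]],
             p_value = p[idx], stringsAsFactors = FALSE)
}

#' Write a model grid to CSV plus a JSON sidecar
#'
#' The CSV mirrors the explorative-model layout: rows are endpoints, columns
#' intercept plus the entropy predictors, cells the p-values with a `*`
#' suffix below the significance threshold, and a trailing `family` column.
#' The JSON sidecar holds the full coefficient tables.
#'
#' @param grid a `model_grid`.
#' @param csv_path,json_path output paths (`NULL` skips either).
#' @export
write_model_grid <- function(grid, csv_path, json_path = NULL) {
  if (!is.null(csv_path)) {
    disp <- matrix(sprintf("%.4g%s", grid$p_values,
                           ifelse(grid$p_values < grid$alpha, "*", "")),
                   nrow(grid$p_values), dimnames = dimnames(grid$p_values))
    disp[is.na(grid$p_values)] <- ""
    out <- cbind(data.frame(endpoint = rownames(disp)),
                 as.data.frame(disp, check.names = FALSE),
                 family = unname(grid$family))
    utils::write.table(out, csv_path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(json_path)) {
    side <- list(
      alpha = grid$alpha, estimator = grid$estimator,
      family = as.list(grid$family), n = as.list(grid$n),
      r_squared = as.list(grid$r_squared),
      converged = as.list(grid$converged),
      coefficients = lapply(grid$coefficients, function(tab) {
        data.frame(term = rownames(tab), estimate = tab[, 1],
                   std_error = tab[, 2], statistic = tab[, 3],
                   p_value = tab[, 4], row.names = NULL)
      }))
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(grid)
}

#' Single-predictor refit of one endpoint on one entropy feature
#'
#' Ordinary least-squares fit of the endpoint on a single entropy predictor,
#' as used to re-examine grid cells that were significant in the adjusted
#' model. Returns the slope with its standard error, two-sided p-value and
#' the coefficient of determination.
#'
#' @param profiles long entropy profiles.
#' @param clinical clinical table.
#' @param endpoint endpoint column name.
#' @param predictor entropy feature name.
#' @param estimator `"point"` or `"shannon"`.
#' @return list of class `single_fit`: `slope`, `std_error`, `intercept`,
#'   `p_value`, `r_squared`, `n`.
#' @export
fit_single_predictor <- function(profiles, clinical, endpoint, predictor,
                                 estimator = c("point", "shannon")) {
  d <- merge_profiles_clinical(profiles, clinical, predictor,
                               match.arg(estimator))
  keep <- stats::complete.cases(d[, c(endpoint, predictor)])
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(d[[predictor]]) == 0)
    stop("constant predictor: ", predictor, call. = FALSE)
  fit <- stats::lm(stats::reformulate(predictor, endpoint), data = d)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[predictor]),
                 std_error = sm$coefficients[predictor, 2],
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = sm$coefficients[predictor, 4],
                 r_squared = sm$r.squared, n = nrow(d)),
            class = "single_fit")
}

#' @export
print.single_fit <- function(x, ...) {
  cat(sprintf("slope %.4g (se %.3g), p = %.4g, R^2 = %.3f, n = %d\n",
              x$slope, x$std_error, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' k-fold cross-validation of a linear model
#'
#' Randomly partitions the complete-case rows into k near-equal folds
#' (seeded shuffle; remainder rows spread one per fold), trains the linear
#' model of `endpoint` on `predictors` on k-1 folds and records the mean
#' squared prediction error on the held-out fold. The full-data training MSE
#' is reported alongside as the overfitting reference: held-out MSE far above
#' it indicates overfitting.
#'
#' @param profiles long entropy profiles.
#' @param clinical clinical table.
#' @param endpoint linear endpoint column name.
#' @param predictors entropy feature names.
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the fold shuffle.
#' @param estimator `"point"` or `"shannon"`.
#' @return list of class `cv_report`: `k`, `seed`, `n`, `fold_sizes`,
#'   `fold_mse`, `mean_mse`, `sd_mse`, `full_data_mse`, `assignment`.
#' @export
kfold_cv <- function(profiles, clinical, endpoint,
                     predictors = default_entropy_features()$variable,
                     k = 3, seed = 1, estimator = c("point", "shannon")) {
  d <- merge_profiles_clinical(profiles, clinical, predictors,
                               match.arg(estimator))
  keep <- stats::complete.cases(d[, c(endpoint, predictors)])
  d <- d[keep, , drop = FALSE]
  n <- nrow(d)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < 2 * k) stop("need n >= 2k complete cases", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
  if (min(table(fold)) < length(predictors) + 1)
    stop("fold smaller than predictor count + 1", call. = FALSE)
  f <- stats::reformulate(predictors, endpoint)
  fold_mse <- vapply(seq_len(k), function(j) {
    fit <- stats::lm(f, data = d[fold != j, , drop = FALSE])
    pred <- stats::predict(fit, newdata = d[fold == j, , drop = FALSE])
    mean((d[[endpoint]][fold == j] - pred)^2)
  }, numeric(1))
  full_fit <- stats::lm(f, data = d)
  structure(list(k = k, seed = seed, n = n,
                 fold_sizes = as.integer(table(fold)),
                 fold_mse = fold_mse, mean_mse = mean(fold_mse),
                 sd_mse = stats::sd(fold_mse),
                 full_data_mse = mean(stats::residuals(full_fit)^2),
                 assignment = stats::setNames(fold, d$case_id)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV (seed %d, n %d): mean held-out MSE %.4g +- %.3g; full-data MSE %.4g\n",
    x$k, x$seed, x$n, x$mean_mse, x$sd_mse, x$full_data_mse))
  invisible(x)
}

#' Write a CV report as JSON
#' @param report a `cv_report`.
#' @param path output path.
#' @export
write_cv_report <- function(report, path) {
  jsonlite::write_json(
    list(k = report$k, seed = report$seed, n = report$n,
         fold_sizes = report$fold_sizes, fold_mse = report$fold_mse,
         mean_mse = report$mean_mse, sd_mse = report$sd_mse,
         full_data_mse = report$full_data_mse),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Does entropy covary with sampling depth?
#'
#' A validity diagnostic for the entropy approach: with few measurement
#' points the attainable entropy is capped ([entropy_max()]), so per-case
#' entropy could spuriously track the number of slides. This check
#' correlates a per-case entropy estimate of one feature with its m.
#'
#' The default estimate is the rarefied Shannon entropy at a common depth
#' ([entropy_rarefied()]), which is free of depth-driven estimator bias: any
#' remaining correlation reflects genuine coupling between heterogeneity and
#' sampling in the cohort. The raw plug-in (`"shannon"`) and the m-scaled
#' per-point sum (`"point"`) are available for comparison; both carry a
#' structural positive dependence on m (bias of order 1/m, and proportional
#' scaling, respectively).
#'
#' @param ct a `case_table` (the slide-level data; needed to rarefy).
#' @param variable feature to check, default `"n_follicle"`.
#' @param staining staining filter; defaults to the feature's entry in
#'   [default_entropy_features()], if any.
#' @param scheme level scheme; defaults to the variable's default scheme.
#' @param estimator `"rarefied"` (default), `"shannon"` or `"point"`.
#' @param depth rarefaction depth; default the smallest per-case m.
#' @return `correlation_result` (r, p, n) with attributes `estimator` and
#'   `depth`.
#' @export
entropy_sample_size_check <- function(ct, variable = "n_follicle",
                                      staining = NULL, scheme = NULL,
                                      estimator = c("rarefied", "shannon",
                                                    "point"),
                                      depth = NULL) {
  estimator <- match.arg(estimator)
  if (is.null(staining)) {
    feats <- default_entropy_features()
    hit <- feats$staining[feats$variable == variable]
    if (length(hit) == 1) staining <- hit
  }
  seqs <- discretize_case(ct, variable, scheme, staining = staining)
  m <- lengths(seqs)
  if (length(seqs) < 3)
    stop("need at least 3 cases with measurement points", call. = FALSE)
  H <- switch(estimator,
    rarefied = {
      if (is.null(depth)) depth <- min(m)
      vapply(seqs, entropy_rarefied, numeric(1), depth = depth)
    },
    shannon = vapply(seqs, entropy_shannon, numeric(1)),
    point = vapply(seqs, entropy_pointsum, numeric(1)))
  res <- pearson_with_p(H, m)
  attr(res, "estimator") <- estimator
  attr(res, "depth") <- if (estimator == "rarefied") depth else NA
  res
}
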