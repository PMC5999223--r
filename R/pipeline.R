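#' Pairwise correlation report of the entropy features
#'
#' The numeric analogue of the cohort-overview panel: per entropy feature a
#' histogram (fixed bins over the observed range) and, for every feature
#' pair, the Pearson correlation with its p-value over complete pairs.
#' Constant features yield `NA` cells, flagged in `undefined`.
#'
#' @param profiles long entropy profiles from [compute_entropy_profiles()].
#' @param estimator `"point"` (default) or `"shannon"`.
#' @param bins number of histogram bins per feature.
#' @return list of class `entropy_matrix`: `correlation` (feature x feature),
#'   `p_values`, `n`, `histograms` (per feature: `breaks`, `counts`),
#'   `undefined` (character vector of constant features).
#' @export
report_entropy_matrix <- function(profiles, estimator = c("point",
                                                          "shannon"),
                                  bins = 10) {
  estimator <- match.arg(estimator)
  wide <- profiles_wide(profiles)
  vars <- unique(profiles$variable)
  H <- as.matrix(wide[, paste0("H_", estimator, "_", vars), drop = FALSE])
  colnames(H) <- vars
  if (nrow(H) < 3) stop("need at least 3 cases", call. = FALSE)
  k <- length(vars)
  corr <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(corr) <- 1
  constant <- vapply(vars, function(v)
    stats::sd(H[, v], na.rm = TRUE) == 0, logical(1))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j || constant[i] || constant[j]) next
    res <- pearson_with_p(H[, i], H[, j])
    corr[i, j] <- res$r
    p[i, j] <- res$p_value
    nmat[i, j] <- res$n
  }
  histograms <- lapply(vars, function(v) {
    x <- H[, v][!is.na(H[, v])]
    h <- graphics::hist(x, breaks = seq(min(x), max(x) + 1e-9,
                                        length.out = bins + 1),
                        plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  names(histograms) <- vars
  structure(list(correlation = corr, p_values = p, n = nmat,
                 histograms = histograms,
                 undefined = vars[constant], estimator = estimator),
            class = "entropy_matrix")
}

#' @export
print.entropy_matrix <- function(x, ...) {
  cat("Pairwise Pearson correlations of entropy features (",
      x$estimator, " estimator):\n", sep = "")
  print(round(x$correlation, 3))
  if (length(x$undefined) > 0)
    cat("undefined (constant) feature(s):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full heterogeneity pipeline
#'
#' One-call orchestration: ingest (or simulate) a cohort, discretize,
#' compute per-case entropies, and write the report bundle into `out_dir`:
#'
#' * `entropies.csv` — per-case entropy table (wide),
#' * `entropy_correlations.csv` / `entropy_histograms.json` — the pairwise
#'   feature-correlation report,
#' * `model_grid.csv` + `model_grid.json` — the explorative endpoint grid,
#' * `single_predictor.csv` — one-predictor refits of significant cells,
#' * `cv_report.json` — k-fold cross-validation of the selected endpoint,
#' * `run_log.txt` — stage log with package version and seed,
#' * for simulated runs additionally `slides.csv`, `clinical.csv`,
#'   `manifest.json`.
#'
#' Exactly one of `slides_path`/`simulate` must be given. Any stage error
#' aborts the run with a stage-named message and removes partial outputs.
#'
#' @param out_dir output directory.
#' @param slides_path,clinical_path input CSVs (ingest mode).
#' @param simulate a [cohort_config()] (simulation mode).
#' @param schemes level schemes, default [default_schemes()].
#' @param features entropy features, default [default_entropy_features()].
#' @param endpoints endpoint table, default [default_endpoints()].
#' @param estimator entropy estimate used downstream (`"point"`/`"shannon"`).
#' @param cv_endpoint endpoint cross-validated (default post-operative
#'   prednisone load).
#' @param cv_k folds (default 3).
#' @param seed integer seed recorded in every output and driving the CV
#'   fold shuffle.
#' @param sep CSV field separator.
#' @return list of class `pipeline_result` with elements `profiles`,
#'   `entropy_matrix`, `model_grid`, `single_fits`, `cv`, `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         slides_path = NULL, clinical_path = NULL,
                         simulate = NULL,
                         schemes = default_schemes(),
                         features = default_entropy_features(),
                         endpoints = default_endpoints(),
                         estimator = c("point", "shannon"),
                         cv_endpoint = "prednisone_post_g", cv_k = 3,
                         seed = 1, sep = ",") {
  estimator <- match.arg(estimator)
  if (is.null(simulate) == is.null(slides_path))
    stop("give exactly one of slides_path or simulate", call. = FALSE)
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) {
    unlink(if (created) out_dir else
      list.files(out_dir, full.names = TRUE), recursive = TRUE)
  }, add = TRUE)
  log_con <- file(file.path(out_dir, "run_log.txt"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_line(log_con, "thymentropy ",
           as.character(utils::packageVersion("thymentropy")),
           " | R ", getRversion(), " | seed ", seed)

  inputs <- stage("ingest", {
    if (!is.null(simulate)) {
      sim <- simulate_cohort(simulate)
      write_cohort(sim, out_dir, sep = sep)
      log_line(log_con, "simulated cohort: ", n_cases(sim$slides),
               " cases (config seed ", simulate$seed, ")")
      list(ct = sim$slides, clinical = sim$clinical)
    } else {
      ct <- read_slide_table(slides_path, sep = sep)
      clinical <- if (!is.null(clinical_path))
        read_clinical_table(clinical_path, sep = sep) else NULL
      log_line(log_con, "ingested ", n_cases(ct), " cases from ",
               slides_path)
      list(ct = ct, clinical = clinical)
    }
  })

  profiles <- stage("entropy", {
    p <- compute_entropy_profiles(inputs$ct, schemes, features)
    write_entropy_table(p, file.path(out_dir, "entropies.csv"))
    p
  })
  log_line(log_con, "entropy profiles: ",
           length(unique(profiles$case_id)), " cases x ",
           length(unique(profiles$variable)), " features")

  emat <- if (length(unique(profiles$case_id)) < 3) {
    log_line(log_con,
             "fewer than 3 cases: entropy correlation report skipped")
    NULL
  } else stage("entropy_matrix", {
    em <- report_entropy_matrix(profiles, estimator = estimator)
    utils::write.table(
      cbind(data.frame(variable = rownames(em$correlation)),
            as.data.frame(round(em$correlation, 6))),
      file.path(out_dir, "entropy_correlations.csv"),
      sep = ",", row.names = FALSE, quote = FALSE, na = "")
    jsonlite::write_json(em$histograms,
                         file.path(out_dir, "entropy_histograms.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    em
  })

  grid <- single_fits <- cv <- NULL
  if (!is.null(inputs$clinical)) {
    grid <- stage("model_grid", {
      g <- fit_model_grid(profiles, inputs$clinical, endpoints,
                          features$variable, estimator = estimator)
      write_model_grid(g, file.path(out_dir, "model_grid.csv"),
                       file.path(out_dir, "model_grid.json"))
      g
    })
    sig <- significant_cells(grid)
    log_line(log_con, "model grid: ", nrow(sig),
             " significant cell(s) at alpha ", grid$alpha)
    single_fits <- stage("single_predictor", {
      fits <- lapply(seq_len(nrow(sig)), function(i)
        fit_single_predictor(profiles, inputs$clinical, sig$endpoint[i],
                             sig$predictor[i], estimator = estimator))
      tab <- if (nrow(sig) == 0) {
        data.frame(endpoint = character(), predictor = character(),
                   slope = numeric(), std_error = numeric(),
                   p_value = numeric(), r_squared = numeric(),
                   n = integer())
      } else {
        cbind(sig[, c("endpoint", "predictor")],
              do.call(rbind, lapply(fits, function(f)
                data.frame(slope = f$slope, std_error = f$std_error,
                           p_value = f$p_value, r_squared = f$r_squared,
                           n = f$n))))
      }
      utils::write.table(tab, file.path(out_dir, "single_predictor.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      fits
    })
    cv <- stage("cross_validation", {
      r <- kfold_cv(profiles, inputs$clinical, cv_endpoint,
                    features$variable, k = cv_k, seed = seed,
                    estimator = estimator)
      write_cv_report(r, file.path(out_dir, "cv_report.json"))
      log_line(log_con, sprintf(
        "%d-fold CV of %s: held-out MSE %.4g +- %.3g (full-data %.4g)",
        r$k, cv_endpoint, r$mean_mse, r$sd_mse, r$full_data_mse))
      r
    })
  } else {
    log_line(log_con, "no clinical table: modelling stages skipped")
  }
  ok <- TRUE
  structure(list(profiles = profiles, entropy_matrix = emat,
                 model_grid = grid, single_fits = single_fits, cv = cv,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result in", x$out_dir, "\n")
  if (!is.null(x$model_grid)) print(x$model_grid)
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}
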