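#' Empirical level distribution of a level sequence
#'
#' @param levels integer (or factor-like) vector of per-point levels, m >= 1.
#' @return list with `counts` (named level -> count), `m` (points) and
#'   `probs` (named level -> relative frequency).
#' @export
level_distribution <- function(levels) {
  if (length(levels) < 1) stop("empty level sequence", call. = FALSE)
  if (anyNA(levels)) stop("NA in level sequence", call. = FALSE)
  u <- sort(unique(levels))
  counts <- tabulate(match(levels, u))
  names(counts) <- as.character(u)
  list(counts = counts, m = length(levels), probs = counts / length(levels))
}

#' Per-point entropy of a level sequence (bit)
#'
#' The package's primary heterogeneity statistic: the sum over the m
#' measurement points of a case of `-p_i * log2(p_i)`, where `p_i` is the
#' empirical relative frequency of the level observed at point i. Points
#' sharing a level contribute identical terms, so the statistic equals
#' `-sum_k c_k * (c_k / m) * log2(c_k / m)` over the occupied levels k with
#' counts `c_k`. A sequence in which every point carries the same level gives
#' exactly 0; the statistic grows with both unevenness and the number of
#' points (see [entropy_max()] for its theoretical ceiling at given m and L).
#'
#' Note this per-point sum is m-scaled: it is not the classical per-level
#' Shannon entropy, which [entropy_shannon()] provides for comparison.
#'
#' @param levels integer vector of per-point levels, m >= 1.
#' @return entropy in bit (non-negative; exactly 0 for constant sequences).
#' @export
#' @examples
#' entropy_pointsum(rep(2, 6))          # 0
#' entropy_pointsum(c(0, 0, 0, 1, 1, 1))  # 3: six terms of -0.5*log2(0.5)
entropy_pointsum <- function(levels) {
  d <- level_distribution(levels)
  if (length(d$counts) == 1) return(0)
  -sum(d$counts * d$probs * log2(d$probs))
}

#' Shannon entropy of a level sequence (bit)
#'
#' The classical plug-in Shannon entropy over levels,
#' `-sum_k p_k log2(p_k)` with `p_k` the empirical level frequencies. Bounded
#' by `log2(min(m, L))`; 0 exactly when all points share one level. No
#' smoothing or bias correction is applied.
#'
#' @inheritParams entropy_pointsum
#' @return entropy in bit.
#' @export
entropy_shannon <- function(levels) {
  d <- level_distribution(levels)
  if (length(d$counts) == 1) return(0)
  -sum(d$probs * log2(d$probs))
}

#' Theoretical maximum of the per-point entropy (bit)
#'
#' Ceiling of [entropy_pointsum()] for a case with `m` measurement points and
#' an `L`-level variable under a uniform level distribution: each of the m
#' terms contributes `-(1/L) * log2(1/L)`, giving `m * (1/L) * log2(L)`. For
#' example, 6 points on a 5-grade variable give 2.786 bit and on a 10-level
#' variable 1.993 bit; with only 3 points and 10 levels the ceiling drops to
#' 0.997 bit — few measurement points cap the attainable entropy, which is
#' why entropy should be checked against sampling depth
#' ([entropy_sample_size_check()]).
#'
#' @param m number of measurement points (>= 1); vectorized.
#' @param n_levels number of possible levels L (>= 1); vectorized.
#' @return maximum entropy in bit (`0` when `n_levels == 1`).
#' @export
#' @examples
#' round(entropy_max(6, 5), 3)   # 2.786
#' round(entropy_max(6, 10), 3)  # 1.993
entropy_max <- function(m, n_levels) {
  stopifnot(all(m >= 1), all(n_levels >= 1))
  ifelse(n_levels == 1, 0, m * (1 / n_levels) * log2(n_levels))
}

#' Rarefied Shannon entropy at a common sampling depth (bit)
#'
#' Expected plug-in Shannon entropy of a without-replacement subsample of
#' `depth` measurement points, computed exactly from the hypergeometric
#' subsampling distribution of each level's count. Because a subsample of
#' exchangeable points is distributed as `depth` points of its own, the
#' rarefied value is comparable across cases with different m — the
#' appropriate quantity when asking whether heterogeneity covaries with
#' sampling depth, where the plug-in estimate's O(1/m) bias would otherwise
#' masquerade as a depth effect.
#'
#' @param levels integer vector of per-point levels.
#' @param depth subsample size, `1 <= depth <= length(levels)`.
#' @return expected Shannon entropy at the given depth, in bit.
#' @export
entropy_rarefied <- function(levels, depth) {
  d <- level_distribution(levels)
  if (depth < 1 || depth > d$m)
    stop("depth must be in [1, m]", call. = FALSE)
  phi <- function(x) ifelse(x == 0, 0, -(x / depth) * log2(x / depth))
  sum(vapply(d$counts, function(ck) {
    x <- 0:min(ck, depth)
    sum(stats::dhyper(x, ck, d$m - ck, depth) * phi(x))
  }, numeric(1)))
}

#' Per-case entropy profiles for a set of features
#'
#' Discretizes each feature with its level scheme, restricted to the staining
#' it is read from, and computes per case: the number of measurement points m,
#' the per-point entropy, the Shannon entropy, and the theoretical maximum
#' [entropy_max()] at that case's m. Cases lacking a feature carry `NA` for
#' it (not zero).
#'
#' @param ct a `case_table`.
#' @param schemes named list of level schemes, default [default_schemes()].
#' @param features data.frame with columns `variable`, `staining`, default
#'   [default_entropy_features()].
#' @return Long data.frame with columns `case_id`, `variable`, `staining`,
#'   `m`, `H_point`, `H_shannon`, `H_max`.
#' @export
compute_entropy_profiles <- function(ct, schemes = default_schemes(),
                                     features = default_entropy_features()) {
  if (n_cases(ct) == 0) stop("empty case table", call. = FALSE)
  ids <- sort(unique(ct$slides$case_id))
  out <- lapply(seq_len(nrow(features)), function(i) {
    v <- features$variable[i]
    st <- features$staining[i]
    scheme <- schemes[[v]]
    if (is.null(scheme)) stop("no level scheme for ", v, call. = FALSE)
    seqs <- if (v %in% names(ct$slides))
      discretize_case(ct, v, scheme, staining = st) else list()
    lv <- seqs[ids]
    present <- !vapply(lv, is.null, logical(1))
    m <- H_point <- H_shannon <- H_max <- rep(NA_real_, length(ids))
    m[present] <- lengths(lv[present])
    H_point[present] <- vapply(lv[present], entropy_pointsum, numeric(1))
    H_shannon[present] <- vapply(lv[present], entropy_shannon, numeric(1))
    H_max[present] <- entropy_max(m[present], scheme$n_levels)
    data.frame(case_id = ids, variable = v, staining = st,
               m = as.integer(m), H_point = H_point,
               H_shannon = H_shannon, H_max = H_max,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pivot entropy profiles to one row per case
#'
#' @param profiles long data.frame from [compute_entropy_profiles()].
#' @param value which entropy column spreads into the `H_<variable>` columns:
#'   `"H_point"` (default) or `"H_shannon"`.
#' @return wide data.frame: `case_id`, then `m_<var>`, `H_point_<var>`,
#'   `H_shannon_<var>`, `H_max_<var>` per feature.
#' @export
profiles_wide <- function(profiles, value = "H_point") {
  ids <- sort(unique(profiles$case_id))
  out <- data.frame(case_id = ids, stringsAsFactors = FALSE)
  for (v in unique(profiles$variable)) {
    p <- profiles[profiles$variable == v, ]
    p <- p[match(ids, p$case_id), ]
    out[[paste0("m_", v)]] <- p$m
    out[[paste0("H_point_", v)]] <- p$H_point
    out[[paste0("H_shannon_", v)]] <- p$H_shannon
    out[[paste0("H_max_", v)]] <- p$H_max
  }
  out
}

#' Write the per-case entropy table as CSV
#' @param profiles long data.frame from [compute_entropy_profiles()].
#' @param path output path.
#' @export
write_entropy_table <- function(profiles, path) {
  utils::write.table(profiles_wide(profiles), path, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
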