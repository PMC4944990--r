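#' Draw a class-restricted random re-pairing
#'
#' Second members are permuted uniformly at random within each class
#' block; first members stay fixed, so every shuffled pair still couples
#' one first member and one second member from the same class (preserving
#' the driver/navigator role structure). The true pairing is not excluded
#' from the support.
#'
#' @param layout A [classroom_layout()].
#' @return Integer vector: for each dyad (in layout order) the id of the
#'   second member assigned to its first member.
#' @export
sample_pairing <- function(layout) {
  layout <- validate_layout(layout)
  out <- integer(nrow(layout))
  for (cl in unique(layout$class_id)) {
    idx <- which(layout$class_id == cl)
    sec <- layout$second_id[idx]
    out[idx] <- if (length(sec) == 1L) sec else sample(sec)
  }
  out
}

#' Permutation null distribution of the mean dyad correlation
#'
#' Repeatedly re-pairs first members with same-class second members and
#' recomputes the mean pair correlation, yielding draws of the null
#' statistic \eqn{\mu_r}.
#'
#' @inheritParams spc_compliance
#' @param n_permutations Number of draws (canonical analysis: 10000).
#' @param seed Optional seed for reproducible draws.
#' @return Numeric vector of `n_permutations` draws of \eqn{\mu_r}. Draws
#'   in which some pairs have undefined correlations average over the
#'   defined ones; the count is returned as attribute `n_undefined_pairs`.
#' @export
null_distribution <- function(fsets, layout, feature = c("HR", "SDNN", "rMSSD"),
                              n_permutations = 10000L, seed = NULL,
                              min_windows = 3L) {
  feature <- match.arg(feature)
  layout <- validate_layout(layout)
  if (!is.null(seed)) set.seed(seed)

  ids <- as.character(c(layout$first_id, layout$second_id))
  missing_ids <- setdiff(ids, names(fsets))
  if (length(missing_ids)) {
    stop("no feature vectors for participant(s): ",
         paste(missing_ids, collapse = ", "))
  }
  # matrix of feature values with invalid windows as NA, one column per
  # participant; correlations then use pairwise-complete windows
  vals <- vapply(fsets, function(f) {
    v <- f[[feature]]
    v[!f$valid] <- NA_real_
    v
  }, numeric(nrow(fsets[[1L]])))

  all_valid <- !anyNA(vals[, ids, drop = FALSE])
  first <- as.character(layout$first_id)
  mu <- numeric(n_permutations)
  undefined <- 0L
  if (all_valid) {
    # fast path: standardise once so each pair correlation is an inner product
    z <- scale(vals[, ids, drop = FALSE])
    const <- attr(z, "scaled:scale") == 0
    z <- sweep(z, 2, sqrt(colSums(z^2)), "/")
    for (b in seq_len(n_permutations)) {
      sec <- as.character(sample_pairing(layout))
      r <- colSums(z[, first, drop = FALSE] * z[, sec, drop = FALSE])
      r[const[first] | const[sec]] <- NA_real_
      if (anyNA(r)) undefined <- undefined + sum(is.na(r))
      mu[b] <- mean(r, na.rm = TRUE)
    }
  } else {
    for (b in seq_len(n_permutations)) {
      sec <- as.character(sample_pairing(layout))
      r <- vapply(seq_along(first), function(d) {
        suppressWarnings(dyad_correlation(vals[, first[d]], vals[, sec[d]],
                                          min_windows = min_windows))
      }, numeric(1))
      if (anyNA(r)) undefined <- undefined + sum(is.na(r))
      if (all(is.na(r))) stop("all pair correlations undefined in a draw")
      mu[b] <- mean(r, na.rm = TRUE)
    }
  }
  attr(mu, "n_undefined_pairs") <- undefined
  mu
}

#' Empirical percentile confidence interval
#'
#' @param mu_samples Draws of the null statistic (>= 100).
#' @param level Coverage (default 0.95).
#' @return Numeric `c(lo, hi)`: the 2.5th and 97.5th (for `level` 0.95)
#'   percentiles under the linear-interpolation percentile definition.
#' @export
percentile_ci <- function(mu_samples, level = 0.95) {
  if (length(mu_samples) < 100L) stop("need at least 100 samples")
  alpha <- (1 - level) / 2
  unname(quantile(mu_samples, c(alpha, 1 - alpha), type = 7))
}

#' Two-tailed Monte-Carlo permutation p-value
#'
#' Add-one smoothed two-tailed p-value of an observed statistic against
#' Monte-Carlo null draws:
#' `p = min(1, 2 * min((1 + #\{mu_r >= mu\}) / (N + 1), (1 + #\{mu_r <= mu\}) / (N + 1)))`.
#' The +1 smoothing avoids reporting exactly zero from finite sampling.
#'
#' @param mu_true Observed statistic.
#' @param mu_samples Null draws.
#' @return p-value in (0, 1].
#' @export
two_tailed_p <- function(mu_true, mu_samples) {
  n <- length(mu_samples)
  if (n == 0L) stop("empty null sample")
  up <- (1 + sum(mu_samples >= mu_true)) / (n + 1)
  lo <- (1 + sum(mu_samples <= mu_true)) / (n + 1)
  min(1, 2 * min(up, lo))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Validating wrapper over `stats::p.adjust(method = "holm")`: the k-th
#' smallest p-value is multiplied by (m - k + 1), cumulative maxima
#' enforce monotonicity, results are capped at 1 and returned in input
#' order.
#'
#' @param p_values Raw p-values, each in (0, 1].
#' @return Adjusted p-values in input order.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))   # 0.03 0.06 0.06
#' @export
holm_bonferroni <- function(p_values) {
  if (!length(p_values)) stop("no p-values supplied")
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "holm")
}

#' Class-restricted permutation test of dyad compliance
#'
#' Fits the compliance statistic \eqn{\mu_{true}} (mean within-dyad
#' Pearson correlation) for each requested HRV feature and tests it
#' against the null that pairings are exchangeable within a class, by
#' permuting second members within class blocks. Two-tailed p-values are
#' Holm-Bonferroni adjusted across the features of this window length
#' (the default family; pass `adjust = FALSE` to adjust elsewhere).
#'
#' @inheritParams spc_compliance
#' @param features HRV features to test (default all three).
#' @param n_permutations Null draws per feature (default 10000).
#' @param seed Optional seed.
#' @param level CI coverage for the null distribution (default 0.95).
#' @param adjust Adjust p-values across `features` (default TRUE).
#' @param keep_samples Keep the null draws in the result (default TRUE;
#'   needed by `plot()`).
#' @return An object of class `"spc_test"`: list with `table` (one row
#'   per feature: `feature`, `mu_true`, `ci_lo`, `ci_hi`, `p_raw`,
#'   `p_adjusted`, `n_dyads`), `compliance` (per-feature
#'   [spc_compliance()] objects), `mu_samples`, `window_length_s`,
#'   `n_permutations`, `seed`.
#' @examples
#' cls <- simulate_classroom(classroom_config(
#'   n_dyads_per_class = c(3, 3), session_length_s = 900, seed = 7))
#' nn <- lapply(names(cls$beats), function(id)
#'   beats_to_nn(cls$beats[[id]], participant_id = as.integer(id)))
#' names(nn) <- names(cls$beats)
#' fs <- features_by_participant(nn, window_spec(300))
#' spc_test(fs, cls$layout, n_permutations = 200, seed = 1)
#' @export
spc_test <- function(fsets, layout, features = c("HR", "SDNN", "rMSSD"),
                     n_permutations = 10000L, seed = NULL, level = 0.95,
                     min_windows = 3L, adjust = TRUE, keep_samples = TRUE) {
  layout <- validate_layout(layout)
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  comp <- samples <- setNames(vector("list", length(features)), features)
  rows <- vector("list", length(features))
  for (i in seq_along(features)) {
    f <- features[i]
    comp[[f]] <- spc_compliance(fsets, layout, f, min_windows = min_windows)
    mu_s <- null_distribution(fsets, layout, f,
                              n_permutations = n_permutations,
                              min_windows = min_windows)
    ci <- percentile_ci(mu_s, level = level)
    rows[[i]] <- data.frame(
      feature = f,
      mu_true = comp[[f]]$mu_true,
      ci_lo = ci[1], ci_hi = ci[2],
      p_raw = two_tailed_p(comp[[f]]$mu_true, mu_s),
      n_dyads = sum(!is.na(comp[[f]]$per_dyad$r))
    )
    if (keep_samples) samples[[f]] <- mu_s
  }
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- if (adjust) holm_bonferroni(tab$p_raw) else tab$p_raw
  structure(list(
    table = tab,
    compliance = comp,
    mu_samples = if (keep_samples) samples else NULL,
    window_length_s = comp[[1L]]$window_length_s,
    n_permutations = n_permutations,
    level = level,
    seed = seed
  ), class = "spc_test")
}

#' @export
print.spc_test <- function(x, digits = 3, ...) {
  cat("Class-restricted permutation test of dyad compliance\n")
  cat("  window ", x$window_length_s, " s, ", x$n_permutations,
      " permutations, ", nrow(x$compliance[[1L]]$per_dyad), " dyads\n",
      sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.spc_test <- function(object, ...) {
  out <- object$table
  out$window_length_s <- object$window_length_s
  out[, c("window_length_s", setdiff(names(out), "window_length_s"))]
}

#' @export
plot.spc_test <- function(x, feature = x$table$feature[1L], ...) {
  if (is.null(x$mu_samples)) {
    stop("test was run with keep_samples = FALSE")
  }
  mu_s <- x$mu_samples[[feature]]
  mu_t <- x$table$mu_true[x$table$feature == feature]
  hist(mu_s, breaks = 50, col = "grey85", border = "white",
       main = paste0("Null distribution of mean pair correlation (",
                     feature, ", ", x$window_length_s, " s)"),
       xlab = expression(mu[r]),
       xlim = range(c(mu_s, mu_t)), ...)
  abline(v = mu_t, col = "firebrick", lwd = 2)
  abline(v = percentile_ci(mu_s, x$level), col = "grey40", lty = 2)
  legend("topright", bty = "n", lwd = c(2, 1), lty = c(1, 2),
         col = c("firebrick", "grey40"),
         legend = c(expression(mu[true]), "null 95% CI"))
  invisible(x)
}
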