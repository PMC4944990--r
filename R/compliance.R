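#' Pearson compliance of one dyad
#'
#' Pearson product-moment correlation of two participants' windowed
#' feature vectors, over pairwise-valid windows only (a window invalid for
#' either member is dropped for both).
#'
#' @param xA,xB Numeric feature vectors on a common window grid.
#' @param validA,validB Logical validity masks (default all valid).
#' @param min_windows Minimum jointly valid windows (default 3).
#' @return The correlation, or `NA_real_` (with a warning) when the joint
#'   support is too short or either series is constant over it.
#' @examples
#' dyad_correlation(c(1, 2, 3), c(1, 2, 4))   # 0.982
#' @export
dyad_correlation <- function(xA, xB, validA = NULL, validB = NULL,
                             min_windows = 3L) {
  if (length(xA) != length(xB)) {
    stop("feature vectors must share a window grid (lengths ",
         length(xA), " vs ", length(xB), ")")
  }
  ok <- !is.na(xA) & !is.na(xB)
  if (!is.null(validA)) ok <- ok & validA
  if (!is.null(validB)) ok <- ok & validB
  if (sum(ok) < min_windows) {
    warning("fewer than ", min_windows, " jointly valid windows")
    return(NA_real_)
  }
  a <- xA[ok]; b <- xB[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant feature vector over the joint support; ",
            "correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Mean dyad correlation (the compliance statistic)
#'
#' @param rs Per-dyad correlations; `NA`s (undefined dyads) are excluded
#'   and counted.
#' @return List with `mu` (arithmetic mean over defined dyads), `n_used`,
#'   `n_excluded`.
#' @examples
#' mean_dyad_correlation(c(0.2, 0.4, NA))$mu   # 0.3
#' @export
mean_dyad_correlation <- function(rs) {
  ok <- !is.na(rs)
  if (!any(ok)) stop("all dyad correlations are undefined")
  list(mu = mean(rs[ok]), n_used = sum(ok), n_excluded = sum(!ok))
}

#' Within-dyad compliance for a classroom
#'
#' Computes the per-dyad Pearson correlations of one windowed HRV feature
#' and their classroom mean, the social psychophysiological compliance
#' statistic.
#'
#' @param fsets Named list of `feature_set`s (see
#'   [features_by_participant()]), indexed by participant id.
#' @param layout A [classroom_layout()].
#' @param feature One of `"HR"`, `"SDNN"`, `"rMSSD"`.
#' @param min_windows Minimum jointly valid windows per dyad.
#' @return An object of class `"spc_compliance"`: list with `per_dyad`
#'   (data frame `dyad_id`, `first_id`, `second_id`, `r`, `n_windows`),
#'   `mu_true`, `feature`, `window_length_s`, `n_excluded`.
#' @export
spc_compliance <- function(fsets, layout, feature = c("HR", "SDNN", "rMSSD"),
                           min_windows = 3L) {
  feature <- match.arg(feature)
  layout <- validate_layout(layout)
  missing_ids <- setdiff(as.character(c(layout$first_id, layout$second_id)),
                         names(fsets))
  if (length(missing_ids)) {
    stop("no feature vectors for participant(s): ",
         paste(missing_ids, collapse = ", "))
  }
  n <- nrow(layout)
  r <- nw <- numeric(n)
  for (d in seq_len(n)) {
    fa <- fsets[[as.character(layout$first_id[d])]]
    fb <- fsets[[as.character(layout$second_id[d])]]
    ok <- fa$valid & fb$valid
    nw[d] <- sum(ok)
    r[d] <- suppressWarnings(
      dyad_correlation(fa[[feature]], fb[[feature]], fa$valid, fb$valid,
                       min_windows = min_windows))
  }
  m <- mean_dyad_correlation(r)
  structure(list(
    per_dyad = data.frame(dyad_id = layout$dyad_id,
                          first_id = layout$first_id,
                          second_id = layout$second_id,
                          r = r, n_windows = as.integer(nw)),
    mu_true = m$mu,
    feature = feature,
    window_length_s = attr(fsets[[1L]], "spec")$length_s,
    n_excluded = m$n_excluded
  ), class = "spc_compliance")
}

#' @export
print.spc_compliance <- function(x, digits = 3, ...) {
  cat("Dyad compliance (", x$feature, ", ", x$window_length_s,
      " s windows)\n", sep = "")
  cat("  mean dyad correlation mu_true = ",
      format(round(x$mu_true, digits)), " over ",
      sum(!is.na(x$per_dyad$r)), " dyads", sep = "")
  if (x$n_excluded > 0) cat(" (", x$n_excluded, " excluded)", sep = "")
  cat("\n  per-dyad r: ",
      paste(format(round(sort(x$per_dyad$r, decreasing = TRUE), 2)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}
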