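#' Dyad sums of self-report items
#'
#' Sums the two members' scores on each 0-10 self-report item: mental
#' demand (MD), temporal demand (TD), performance (Pe), effort (Ef),
#' frustration (Fr) and concentration while navigating (Na).
#'
#' @param reports Data frame with `participant_id` and the six item
#'   columns, integer 0-10.
#' @param layout A [classroom_layout()].
#' @return Data frame `dyad_id`, `MD`, `TD`, `Pe`, `Ef`, `Fr`, `Na`, each
#'   sum in 0-20.
#' @export
dyad_sums <- function(reports, layout) {
  layout <- validate_layout(layout)
  items <- c("MD", "TD", "Pe", "Ef", "Fr", "Na")
  missing_cols <- setdiff(c("participant_id", items), names(reports))
  if (length(missing_cols)) {
    stop("reports are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  row_of <- match(c(layout$first_id, layout$second_id),
                  reports$participant_id)
  if (anyNA(row_of)) {
    bad <- c(layout$first_id, layout$second_id)[is.na(row_of)]
    stop("no self-report for participant(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(dyad_id = layout$dyad_id)
  n <- nrow(layout)
  for (it in items) {
    v <- reports[[it]][row_of]
    if (anyNA(v)) {
      d <- layout$dyad_id[((which(is.na(v)) - 1L) %% n) + 1L][1L]
      stop("missing item ", it, " in dyad ", d)
    }
    if (any(v < 0 | v > 10)) {
      stop("item ", it, " outside the 0-10 scale")
    }
    out[[it]] <- v[seq_len(n)] + v[n + seq_len(n)]
  }
  out
}

#' Linear model of dyad compliance on summed self-reports
#'
#' Ordinary least squares of the per-dyad compliance correlation on the
#' six dyad-summed self-report items (physical demand is excluded as
#' irrelevant to the task):
#' \deqn{r_d = \beta_0 + \beta_m MD_d + \beta_t TD_d + \beta_p Pe_d +
#'       \beta_e Ef_d + \beta_f Fr_d + \beta_n Na_d + \epsilon_d .}
#' Confidence intervals are t-based with `n_dyads - 7` degrees of
#' freedom, as in a standard linear-model summary.
#'
#' @param sums Dyad item sums from [dyad_sums()] (or any data frame with
#'   the six item columns, one row per dyad in layout order).
#' @param r Response: either an [spc_compliance()] object or a numeric
#'   vector of per-dyad correlations parallel to `sums`.
#' @param level CI coverage (default 0.95).
#' @return An object of class `"spc_lm"`: list with `fit` (the underlying
#'   `lm`), `table` (per-term estimate, SE, CI), `adj_r2`, `n_dyads`,
#'   `feature`, `window_length_s`, `level`. Supports `coef()`,
#'   `predict()`, `residuals()`, `fitted()`, `summary()` and `plot()`.
#' @examples
#' d <- study_dyads()
#' fit <- spc_lm(d, d$rMSSD_300)
#' coef(fit)["TD"]          # about -0.15
#' fit$adj_r2               # about 0.50
#' @export
spc_lm <- function(sums, r, level = 0.95) {
  feature <- window_length_s <- NA
  if (inherits(r, "spc_compliance")) {
    feature <- r$feature
    window_length_s <- r$window_length_s
    r <- r$per_dyad$r
  }
  items <- c("MD", "TD", "Pe", "Ef", "Fr", "Na")
  if (!all(items %in% names(sums))) {
    stop("sums must contain columns ", paste(items, collapse = ", "))
  }
  dat <- sums[items]
  dat$r <- r
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 8L) stop("need at least 8 dyads (got ", n, ")")
  fit <- lm(r ~ MD + TD + Pe + Ef + Fr + Na, data = dat)
  if (fit$rank < 7L) {
    ali <- names(which(is.na(coef(fit))))
    stop("rank-deficient design; collinear term(s): ",
         paste(ali, collapse = ", "))
  }
  s <- summary(fit)
  ci <- confint(fit, level = level)
  tab <- data.frame(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, 1],
    std_error = s$coefficients[, 2],
    ci_lo = ci[, 1], ci_hi = ci[, 2],
    p_value = s$coefficients[, 4],
    row.names = NULL
  )
  structure(list(fit = fit, table = tab,
                 adj_r2 = s$adj.r.squared,
                 n_dyads = n, feature = feature,
                 window_length_s = window_length_s, level = level),
            class = "spc_lm")
}

#' @export
print.spc_lm <- function(x, digits = 3, ...) {
  cat("Compliance ~ summed self-reports (OLS, ", x$n_dyads, " dyads",
      sep = "")
  if (!is.na(x$feature)) {
    cat("; ", x$feature, ", ", x$window_length_s, " s windows", sep = "")
  }
  cat(")\n  adjusted R-squared: ", round(x$adj_r2, digits), "\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.spc_lm <- function(object, ...) summary(object$fit, ...)

#' @export
coef.spc_lm <- function(object, ...) {
  cf <- coef(object$fit)
  names(cf) <- sub("^\\(Intercept\\)$", "(Intercept)", names(cf))
  cf
}

#' @export
predict.spc_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$fit, ...)
  else predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.spc_lm <- function(object, ...) residuals(object$fit, ...)

#' @export
fitted.spc_lm <- function(object, ...) fitted(object$fit, ...)

#' @export
plot.spc_lm <- function(x, ...) {
  obs <- x$fit$model$r
  plot(fitted(x), obs,
       xlab = "fitted dyad correlation", ylab = "observed dyad correlation",
       main = "Compliance regression fit", ...)
  abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Per-participant mean of a summed self-report item
#'
#' Recovers the participant-level mean of an item from dyad sums:
#' total of the sums divided by twice the dyad count.
#'
#' @param sums Dyad sums (see [dyad_sums()]).
#' @param item Item name, e.g. `"MD"`.
#' @return The per-participant mean.
#' @examples
#' population_item_mean(study_dyads(), "MD")   # about 6.0
#' @export
population_item_mean <- function(sums, item) {
  if (!item %in% names(sums)) stop("unknown item: ", item)
  if (!nrow(sums)) stop("no dyads")
  sum(sums[[item]]) / (2 * nrow(sums))
}
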