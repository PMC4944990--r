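#' Sliding-window specification
#'
#' Windows of a fixed length slide over the session with an overlap that
#' defaults to one third of the window length (step = 2/3 of the length).
#' Only complete windows are formed; intervals are half-open
#' `[start, start + length)`.
#'
#' @param length_s Window length in seconds. The canonical analysis grid
#'   is 60 to 300 s in 40 s steps.
#' @param overlap_s Overlap between consecutive windows (default
#'   `length_s / 3`); must satisfy `0 <= overlap_s < length_s`.
#' @param origin_s Analysis start time (default 0 = recording start).
#' @return An object of class `"window_spec"`.
#' @examples
#' window_spec(300)          # step 200 s
#' window_spec(60, overlap_s = 20)
#' @export
window_spec <- function(length_s, overlap_s = length_s / 3, origin_s = 0) {
  if (length_s <= 0) stop("window length must be positive")
  if (overlap_s < 0 || overlap_s >= length_s) {
    stop("overlap must satisfy 0 <= overlap < length")
  }
  structure(list(length_s = length_s, overlap_s = overlap_s,
                 origin_s = origin_s,
                 step_s = length_s - overlap_s),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("Window spec: length ", x$length_s, " s, overlap ", x$overlap_s,
      " s (step ", x$step_s, " s), origin ", x$origin_s, " s\n", sep = "")
  invisible(x)
}

#' Enumerate complete sliding windows over a recording
#'
#' @param duration_s Recording duration in seconds.
#' @param spec A [window_spec()].
#' @return Data frame with columns `start_s`, `end_s`; zero rows when the
#'   window does not fit.
#' @examples
#' make_windows(900, window_spec(300, overlap_s = 100))  # starts 0,200,400,600
#' @export
make_windows <- function(duration_s, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (duration_s <= 0) stop("duration_s must be positive")
  last_start <- duration_s - spec$length_s
  if (last_start < spec$origin_s) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  # tolerate floating-point shortfall at the final window boundary
  starts <- seq(spec$origin_s, last_start + 1e-9, by = spec$step_s)
  data.frame(start_s = starts, end_s = starts + spec$length_s)
}

#' Time-domain HRV features of one window
#'
#' `hr_feature()` is heart rate as the inverse of the mean NN interval;
#' `sdnn_feature()` the sample standard deviation of NN intervals;
#' `rmssd_feature()` the root mean square of successive NN differences,
#' taken only between temporally adjacent accepted intervals (an artifact
#' rejection breaks adjacency). Windows with too few beats return `NA`
#' rather than raising.
#'
#' @param nn_ms NN intervals in the window, ms.
#' @param min_beats Minimum interval count for a defined value
#'   (defaults: 10 for HR, 2 for SDNN, 3 for rMSSD).
#' @param adjacent Logical vector, `adjacent[k]` indicating that interval
#'   `k` immediately follows interval `k - 1` in the raw series (first
#'   element ignored). Default: all adjacent.
#' @return A scalar in bpm (HR) or ms (SDNN, rMSSD); `NA_real_` when the
#'   window is invalid.
#' @examples
#' hr_feature(rep(800, 20))              # 75 bpm
#' sdnn_feature(c(800, 850, 900))        # 50 ms
#' rmssd_feature(c(800, 900, 800))       # 100 ms
#' @export
hr_feature <- function(nn_ms, min_beats = 10L) {
  if (length(nn_ms) < max(1L, min_beats)) return(NA_real_)
  60000 / mean(nn_ms)
}

#' @rdname hr_feature
#' @export
sdnn_feature <- function(nn_ms, min_beats = 2L) {
  if (length(nn_ms) < max(2L, min_beats)) return(NA_real_)
  sd(nn_ms)
}

#' @rdname hr_feature
#' @export
rmssd_feature <- function(nn_ms, min_beats = 3L, adjacent = NULL) {
  if (length(nn_ms) < max(3L, min_beats)) return(NA_real_)
  d <- diff(nn_ms)
  if (!is.null(adjacent)) d <- d[adjacent[-1L]]
  if (length(d) < 2L) return(NA_real_)
  sqrt(mean(d^2))
}

#' Windowed feature matrix for one participant
#'
#' Applies [hr_feature()], [sdnn_feature()] and [rmssd_feature()] over the
#' windows given by `spec`. A window is valid when it contains at least
#' `min_beats` NN intervals; validity is shared by the three features so
#' dyad comparisons use a common support. Invalid windows are flagged, not
#' dropped.
#'
#' @param nn An `nn_series` (see [filter_abnormal()]).
#' @param spec A [window_spec()].
#' @param min_beats Minimum NN intervals per valid window (default 10).
#' @param duration_s Analysis span; defaults to the last interval time.
#' @return A `feature_set`: data frame with columns `window_start_s`,
#'   `n_beats`, `valid`, `HR`, `SDNN`, `rMSSD`, with the spec and
#'   participant id as attributes.
#' @examples
#' nn <- beats_to_nn(cumsum(rep(0.8, 2251)))
#' fs <- feature_matrix(nn, window_spec(300), duration_s = 1800)
#' nrow(fs)      # 8 windows
#' @export
feature_matrix <- function(nn, spec, min_beats = 10L, duration_s = NULL) {
  if (nrow(nn) == 0L) {
    stop("empty NN series (participant ",
         attr(nn, "participant_id"), ")")
  }
  if (is.null(duration_s)) duration_s <- max(nn$time_s)
  win <- make_windows(duration_s, spec)
  if (nrow(win) == 0L) {
    stop("NN series shorter than one window (participant ",
         attr(nn, "participant_id"), ": ", round(duration_s, 1),
         " s < ", spec$length_s, " s)")
  }
  m <- nrow(win)
  hr <- sdnn <- rmssd <- rep(NA_real_, m)
  nb <- integer(m)
  adj <- c(TRUE, diff(nn$raw_index) == 1L)
  # windows are ordered; locate each window's interval range by binary search
  lo <- findInterval(win$start_s, nn$time_s, left.open = TRUE) + 1L
  hi <- findInterval(win$end_s - 1e-9, nn$time_s)
  for (w in seq_len(m)) {
    if (hi[w] < lo[w]) next
    idx <- lo[w]:hi[w]
    nb[w] <- length(idx)
    if (nb[w] < min_beats) next
    v <- nn$nn_ms[idx]
    hr[w] <- hr_feature(v, min_beats = 1L)
    sdnn[w] <- sdnn_feature(v)
    rmssd[w] <- rmssd_feature(v, adjacent = adj[idx])
  }
  valid <- nb >= min_beats & !is.na(hr) & !is.na(sdnn) & !is.na(rmssd)
  out <- data.frame(window_start_s = win$start_s, n_beats = nb,
                    valid = valid, HR = hr, SDNN = sdnn, rMSSD = rmssd)
  attr(out, "spec") <- spec
  attr(out, "participant_id") <- attr(nn, "participant_id")
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Linear session trend of a windowed feature
#'
#' Ordinary least-squares slope of a feature against window start time,
#' over valid windows only. Used to characterise classroom-wide drifts
#' (e.g. gradually decreasing heart rate over a session).
#'
#' @param fv A `feature_set` from [feature_matrix()].
#' @param feature One of `"HR"`, `"SDNN"`, `"rMSSD"`.
#' @return List with `slope` (units per second), `intercept`, `n_windows`;
#'   slope and intercept are `NA` with fewer than 3 valid windows.
#' @export
linear_trend <- function(fv, feature = c("HR", "SDNN", "rMSSD")) {
  feature <- match.arg(feature)
  ok <- fv$valid & !is.na(fv[[feature]])
  n <- sum(ok)
  if (n < 3L) {
    return(list(slope = NA_real_, intercept = NA_real_, n_windows = n))
  }
  t <- fv$window_start_s[ok]
  y <- fv[[feature]][ok]
  b <- cov(t, y) / var(t)
  list(slope = b, intercept = mean(y) - b * mean(t), n_windows = n)
}

#' Windowed features for every participant of a classroom
#'
#' @param nn_list Named list of `nn_series`, one per participant.
#' @param spec A [window_spec()].
#' @param min_beats Minimum NN intervals per valid window.
#' @param duration_s Common analysis span; defaults to the shortest
#'   participant span so all feature vectors share a window grid.
#' @return Named list of `feature_set`s on a common window grid.
#' @export
features_by_participant <- function(nn_list, spec, min_beats = 10L,
                                    duration_s = NULL) {
  if (is.null(duration_s)) {
    duration_s <- min(vapply(nn_list, function(nn) max(nn$time_s),
                             numeric(1)))
  }
  lapply(nn_list, feature_matrix, spec = spec, min_beats = min_beats,
         duration_s = duration_s)
}
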