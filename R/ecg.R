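#' Detect R-peaks in a single-channel ECG
#'
#' A dependency-light QRS detector in the band-pass /
#' differentiate / square / integrate family: the signal is band-pass
#' filtered (5-15 Hz, zero-phase Butterworth), differentiated, squared and
#' smoothed with a 150 ms moving-average window; candidate peaks are local
#' maxima of the smoothed energy exceeding an adaptively updated
#' signal/noise threshold, subject to a 250 ms refractory period. Each
#' accepted candidate is refined to the local maximum of the *raw* signal
#' within +/- 40 ms.
#'
#' @param samples Numeric voltage series (mV).
#' @param sampling_rate Sampling rate in Hz (>= 100).
#' @param start_offset_s Time of the first sample relative to session
#'   start; added to the returned peak times.
#' @param refractory_s Minimum separation between accepted peaks
#'   (default 0.25 s).
#' @param refine_s Half-width of the raw-signal refinement window
#'   (default 0.04 s).
#' @param on_flat What to do with a flat (zero-variance) signal:
#'   `"empty"` (default) returns no peaks, `"error"` raises.
#' @return Numeric vector of strictly increasing R-peak times in seconds.
#' @examples
#' ecg <- synthesize_ecg(seq(1, 10), sampling_rate = 250)
#' detect_r_peaks(ecg$samples, 250)
#' @export
detect_r_peaks <- function(samples, sampling_rate, start_offset_s = 0,
                           refractory_s = 0.25, refine_s = 0.04,
                           on_flat = c("empty", "error")) {
  on_flat <- match.arg(on_flat)
  if (sampling_rate < 100) stop("sampling_rate must be >= 100 Hz")
  n <- length(samples)
  if (n < 10 * sampling_rate) {
    stop("recording too short for peak detection (need >= 10 s, got ",
         round(n / sampling_rate, 2), " s)")
  }
  if (sd(samples) == 0) {
    if (on_flat == "error") stop("flat signal: no QRS energy detected")
    return(numeric(0))
  }

  nyq <- sampling_rate / 2
  bf <- signal::butter(3, c(5, 15) / nyq, type = "pass")
  filt <- signal::filtfilt(bf, samples)
  energy <- c(0, diff(filt))^2
  win <- max(3L, round(0.150 * sampling_rate))
  integ <- as.numeric(stats::filter(energy, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0

  # local maxima of the integrated energy
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(cand)) {
    if (on_flat == "error") stop("no candidate peaks found")
    return(numeric(0))
  }
  # adaptive signal / noise running estimates (Pan-Tompkins style)
  spk <- as.numeric(quantile(integ[cand], 0.95))
  npk <- as.numeric(quantile(integ[cand], 0.50))
  refr <- refractory_s * sampling_rate
  accepted <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npk + 0.25 * (spk - npk)
    if (integ[i] > thr && (i - last) > refr) {
      accepted <- c(accepted, i)
      last <- i
      spk <- 0.875 * spk + 0.125 * integ[i]
    } else if (integ[i] <= thr) {
      npk <- 0.875 * npk + 0.125 * integ[i]
    }
  }
  if (!length(accepted)) return(numeric(0))

  # two-stage refinement: the energy envelope has a broad plateau, so
  # first snap to the band-passed QRS within half the integration window,
  # then to the raw-signal maximum in a +/- refine_s neighbourhood
  half1 <- max(1L, win %/% 2L)
  half <- round(refine_s * sampling_rate)
  peaks <- vapply(accepted, function(i) {
    idx <- max(1L, i - half1):min(n, i + half1)
    j <- idx[which.max(abs(filt[idx]))]
    idx <- max(1L, j - half):min(n, j + half)
    idx[which.max(samples[idx])]
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory period after refinement
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) > refr)
    while (!all(keep)) {
      peaks <- peaks[keep]
      keep <- c(TRUE, diff(peaks) > refr)
    }
  }
  (peaks - 1) / sampling_rate + start_offset_s
}

#' Interbeat intervals from R-peak times
#'
#' @param peak_times_s Strictly increasing R-peak times in seconds.
#' @return Data frame with columns `time_s` (the terminating beat of each
#'   interval) and `ibi_ms`; empty when fewer than two peaks.
#' @examples
#' peaks_to_ibi(c(0, 0.8, 1.7))   # 800 and 900 ms
#' @export
peaks_to_ibi <- function(peak_times_s) {
  if (length(peak_times_s) < 2L) {
    return(data.frame(time_s = numeric(0), ibi_ms = numeric(0)))
  }
  if (any(diff(peak_times_s) <= 0)) {
    stop("peak times must be strictly increasing")
  }
  data.frame(
    time_s = peak_times_s[-1L],
    ibi_ms = 1000 * diff(peak_times_s)
  )
}

#' Filter abnormal interbeat intervals to a normal-to-normal series
#'
#' Abnormal beats are excluded, not interpolated: an interval is rejected
#' when it falls outside the physiological band or deviates more than
#' `max_rel_dev` from the running median of the previous (up to 10)
#' accepted intervals. The deviation rule engages once at least
#' `min_history` intervals have been accepted. A rejected interval breaks
#' temporal adjacency, which [rmssd_feature()] respects when forming
#' successive differences.
#'
#' @param ibi A data frame from [peaks_to_ibi()] (columns `time_s`,
#'   `ibi_ms`), or a numeric vector of intervals in ms (then timestamped
#'   by their cumulative sum).
#' @param band Acceptance band in ms (default `c(300, 2000)`).
#' @param max_rel_dev Maximum relative deviation from the running median
#'   (default 0.3).
#' @param history Number of previous accepted intervals in the running
#'   median (default 10).
#' @param min_history Accepted intervals required before the deviation
#'   rule applies (default 5).
#' @param participant_id Optional id attached to the result.
#' @return An `nn_series`: data frame with columns `time_s`, `nn_ms`,
#'   `raw_index` (position in the input, so `diff(raw_index) == 1` marks
#'   temporally adjacent accepted intervals), with attributes
#'   `rejected_count` and `participant_id`. Filtering is idempotent.
#' @examples
#' ibi <- peaks_to_ibi(cumsum(c(0, rep(0.8, 20))))
#' ibi$ibi_ms[10] <- 250          # implausibly short beat
#' nn <- filter_abnormal(ibi)
#' attr(nn, "rejected_count")     # 1
#' @export
filter_abnormal <- function(ibi, band = c(300, 2000), max_rel_dev = 0.3,
                            history = 10L, min_history = 5L,
                            participant_id = NA_integer_) {
  if (is.numeric(ibi)) {
    ibi <- data.frame(time_s = cumsum(ibi) / 1000, ibi_ms = ibi)
  }
  x <- ibi$ibi_ms
  n <- length(x)
  if (n == 0L) {
    out <- data.frame(time_s = numeric(0), nn_ms = numeric(0),
                      raw_index = integer(0))
    attr(out, "rejected_count") <- 0L
    attr(out, "participant_id") <- participant_id
    class(out) <- c("nn_series", "data.frame")
    return(out)
  }
  accept <- .filter_nn_accept(as.numeric(x), band[1], band[2],
                              max_rel_dev, as.integer(history),
                              as.integer(min_history))

  out <- data.frame(time_s = ibi$time_s[accept], nn_ms = x[accept],
                    raw_index = which(accept))
  attr(out, "rejected_count") <- as.integer(n - sum(accept))
  attr(out, "participant_id") <- participant_id
  class(out) <- c("nn_series", "data.frame")
  out
}

#' @export
print.nn_series <- function(x, ...) {
  cat("NN series: ", nrow(x), " intervals, ",
      attr(x, "rejected_count"), " rejected", sep = "")
  pid <- attr(x, "participant_id")
  if (!is.na(pid)) cat(" (participant ", pid, ")", sep = "")
  cat("\n")
  if (nrow(x)) {
    cat("  span ", round(min(x$time_s), 1), "-", round(max(x$time_s), 1),
        " s, mean NN ", round(mean(x$nn_ms), 1), " ms\n", sep = "")
  }
  invisible(x)
}

#' Beat times to a filtered NN series in one step
#'
#' Convenience composition of [peaks_to_ibi()] and [filter_abnormal()],
#' used when beats are already available (e.g. generator output).
#'
#' @inheritParams peaks_to_ibi
#' @inheritParams filter_abnormal
#' @param ... Passed to [filter_abnormal()].
#' @return An `nn_series`.
#' @export
beats_to_nn <- function(peak_times_s, participant_id = NA_integer_, ...) {
  filter_abnormal(peaks_to_ibi(peak_times_s),
                  participant_id = participant_id, ...)
}
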