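#' Configuration for the synthetic classroom generator
#'
#' Builds a validated parameter set for [simulate_classroom()]. The
#' generator emulates a classroom of pair-programming dyads wearing
#' single-channel ECG: each participant's interbeat intervals (IBIs) are a
#' base level, plus a slow classroom-wide heart-rate drift (relaxation over
#' the session), plus beat-level noise whose *dispersion* is modulated by a
#' slow latent process that dyad members partially share. Coupling enters
#' through the dispersion latent only, never the mean IBI, so windowed SDNN
#' compliance is pairing-specific while HR correlations are driven by the
#' shared drift regardless of pairing.
#'
#' @param n_dyads_per_class Integer vector, dyads per class (room).
#'   Default `c(5, 5, 5, 4)`: 19 dyads, 38 participants.
#' @param session_length_s Session duration in seconds (default 5400,
#'   i.e. a ~90 minute session including baseline and preparation).
#' @param base_ibi_ms Mean interbeat interval in ms (default 800, 75 bpm).
#'   Must lie in (300, 2000).
#' @param coupling Per-dyad coupling \eqn{\kappa \in [0, 1]}: the fraction
#'   of each member's dispersion-latent variance that is shared within the
#'   dyad. Scalar (recycled) or one value per dyad. Default: evenly spaced
#'   from 0.1 to 0.9 across dyads, so collaboration quality varies across
#'   the classroom.
#' @param hr_trend_slope_bpm_per_min Classroom-common heart-rate drift in
#'   bpm per minute (default -0.05; negative = gradual relaxation).
#' @param trend_participation Fraction of participants expressing the
#'   common drift (default 0.8), assigned independently of the pairing so
#'   the drift-driven heart-rate correlation is pairing-independent.
#' @param sdnn_latent_timescale_s Autocorrelation timescale of the slow
#'   dispersion latent, seconds (default 120).
#' @param noise_sd_ms Baseline beat-level noise SD in ms (default 15).
#' @param mean_wander_ms SD of a slow, participant-private wander of the
#'   mean IBI, ms (default 10). Keeps heart-rate correlations below 1.
#' @param dispersion_gain Log-scale gain of the latent on the beat-noise
#'   SD (default 0.5): instantaneous SD is
#'   `noise_sd_ms * exp(gain * L - gain^2 / 2)` for unit-variance latent L.
#' @param tlx_temporal_effect Slope of the expected *dyad sum* of the
#'   temporal-demand item on \eqn{\kappa} (default -6: stronger coupling,
#'   less felt time pressure).
#' @param seed Integer RNG seed; a single stream drives the whole
#'   classroom so identical configs reproduce identical output.
#'
#' @return An object of class `"classroom_config"` (a named list).
#' @seealso [simulate_classroom()]
#' @export
classroom_config <- function(n_dyads_per_class = c(5, 5, 5, 4),
                             session_length_s = 5400,
                             base_ibi_ms = 800,
                             coupling = NULL,
                             hr_trend_slope_bpm_per_min = -0.05,
                             trend_participation = 0.8,
                             sdnn_latent_timescale_s = 120,
                             noise_sd_ms = 15,
                             mean_wander_ms = 10,
                             dispersion_gain = 0.5,
                             tlx_temporal_effect = -6,
                             seed = 1L) {
  n_dyads_per_class <- as.integer(n_dyads_per_class)
  if (length(n_dyads_per_class) < 1L || any(n_dyads_per_class < 1L)) {
    stop("n_dyads_per_class must be positive integers")
  }
  n_dyads <- sum(n_dyads_per_class)
  if (is.null(coupling)) {
    coupling <- if (n_dyads == 1L) 0.5 else seq(0.1, 0.9, length.out = n_dyads)
  }
  coupling <- rep_len(coupling, n_dyads)
  if (any(coupling < 0 | coupling > 1)) {
    stop("coupling values must lie in [0, 1]")
  }
  if (!(base_ibi_ms > 300 && base_ibi_ms < 2000)) {
    stop("base_ibi_ms must lie in (300, 2000)")
  }
  if (session_length_s <= 300) {
    stop("session_length_s must exceed the largest analysis window (300 s)")
  }
  if (trend_participation < 0 || trend_participation > 1) {
    stop("trend_participation must lie in [0, 1]")
  }
  if (sdnn_latent_timescale_s <= 0 || noise_sd_ms <= 0) {
    stop("sdnn_latent_timescale_s and noise_sd_ms must be positive")
  }
  structure(list(
    n_dyads_per_class = n_dyads_per_class,
    session_length_s = session_length_s,
    base_ibi_ms = base_ibi_ms,
    coupling = coupling,
    hr_trend_slope_bpm_per_min = hr_trend_slope_bpm_per_min,
    trend_participation = trend_participation,
    sdnn_latent_timescale_s = sdnn_latent_timescale_s,
    noise_sd_ms = noise_sd_ms,
    mean_wander_ms = mean_wander_ms,
    dispersion_gain = dispersion_gain,
    tlx_temporal_effect = tlx_temporal_effect,
    seed = seed
  ), class = "classroom_config")
}

# Stationary AR(1) (discretised Ornstein-Uhlenbeck) path, unit variance,
# on a grid with spacing dt_s and autocorrelation timescale tau_s.
ou_path <- function(n, tau_s, dt_s = 1) {
  a <- exp(-dt_s / tau_s)
  innov <- rnorm(n) * sqrt(1 - a^2)
  as.numeric(stats::filter(innov, a, method = "recursive", init = rnorm(1)))
}

# Population means/SDs of the self-report items (0-10 scales) used by the
# generator; temporal demand additionally depends on dyad coupling.
.tlx_item_params <- list(
  MD = c(mean = 6.0, sd = 2.05),
  TD = c(mean = 6.0, sd = 1.88),
  Pe = c(mean = 6.4, sd = 2.50),
  Ef = c(mean = 6.3, sd = 2.62),
  Fr = c(mean = 4.2, sd = 2.91),
  Na = c(mean = 8.1, sd = 1.69)
)

#' Simulate a classroom of coupled dyadic beat series and self-reports
#'
#' Generates per-participant beat times, a classroom layout, and
#' NASA-TLX-style self-reports with known ground truth, suitable as input
#' to the full compliance pipeline. See [classroom_config()] for the data
#' model. All randomness comes from one stream seeded by `config$seed`;
#' identical configs give bitwise-identical output.
#'
#' @param config A [classroom_config()].
#' @return An object of class `"classroom"`: a list with elements
#'   \describe{
#'     \item{beats}{named list (by participant id) of strictly increasing
#'       beat times in seconds}
#'     \item{layout}{a [classroom_layout()]}
#'     \item{reports}{data frame of integer items `MD, TD, Pe, Ef, Fr, Na`
#'       (0-10) per participant}
#'     \item{truth}{generator ground truth: per-dyad `coupling`, dyad
#'       `trend` flags, and the per-participant dispersion-latent paths on
#'       a 1 s grid (for recovery tests)}
#'     \item{config}{the input configuration}
#'   }
#' @examples
#' cls <- simulate_classroom(classroom_config(
#'   n_dyads_per_class = c(2, 2), session_length_s = 600, seed = 42))
#' length(cls$beats)           # 8 participants
#' head(cls$beats[["1"]])
#' @export
simulate_classroom <- function(config = classroom_config()) {
  if (!inherits(config, "classroom_config")) {
    stop("config must be created with classroom_config()")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  n_dyads <- sum(config$n_dyads_per_class)
  n_part <- 2L * n_dyads
  layout <- classroom_layout(
    first_id = seq_len(n_dyads),
    second_id = seq_len(n_dyads) + n_dyads,
    class_id = rep(seq_along(config$n_dyads_per_class),
                   config$n_dyads_per_class)
  )

  # participant-level trend flags, independent of the pairing: the drift
  # is a classroom-wide process, not a dyad-specific one
  n_trend <- round(config$trend_participation * n_part)
  trend_participants <- rep(FALSE, n_part)
  trend_participants[sample.int(n_part, n_trend)] <- TRUE

  grid_n <- ceiling(config$session_length_s) + 1L
  grid_t <- seq_len(grid_n) - 1

  # latent paths on a 1 s grid: one shared path per dyad, one private path
  # and one mean-wander path per participant
  tau <- config$sdnn_latent_timescale_s
  shared <- lapply(seq_len(n_dyads), function(d) ou_path(grid_n, tau))
  disp_latent <- vector("list", n_part)
  wander <- vector("list", n_part)
  for (d in seq_len(n_dyads)) {
    k <- config$coupling[d]
    for (pid in c(layout$first_id[d], layout$second_id[d])) {
      private <- ou_path(grid_n, tau)
      disp_latent[[pid]] <- sqrt(k) * shared[[d]] + sqrt(1 - k) * private
      wander[[pid]] <- ou_path(grid_n, tau)
    }
  }

  hr0 <- 60000 / config$base_ibi_ms
  slope <- config$hr_trend_slope_bpm_per_min
  gain <- config$dispersion_gain
  n_max <- ceiling(config$session_length_s * 1000 / (0.65 * config$base_ibi_ms))

  beats <- vector("list", n_part)
  names(beats) <- as.character(seq_len(n_part))
  for (pid in seq_len(n_part)) {
    z <- rnorm(n_max)
    # two fixed-point passes: beat times depend on IBIs which depend on
    # the (slow) latents evaluated at the beat times
    t_k <- seq_len(n_max) * config$base_ibi_ms / 1000
    for (pass in 1:2) {
      t_c <- pmin(t_k, config$session_length_s)
      mean_ibi <- if (trend_participants[pid])
        60000 / (hr0 + slope * t_c / 60) else
        rep(config$base_ibi_ms, n_max)
      L <- approx(grid_t, disp_latent[[pid]], xout = t_c, rule = 2)$y
      W <- approx(grid_t, wander[[pid]], xout = t_c, rule = 2)$y
      sd_t <- config$noise_sd_ms * exp(gain * L - gain^2 / 2)
      ibi <- mean_ibi + config$mean_wander_ms * W + sd_t * z
      ibi <- pmin(pmax(ibi, 301), 1999)
      t_k <- cumsum(ibi) / 1000
    }
    beats[[pid]] <- t_k[t_k <= config$session_length_s]
  }

  # self-reports: temporal demand decreases in dyad coupling, the other
  # items are independent of it
  reports <- data.frame(participant_id = seq_len(n_part))
  kappa_of <- numeric(n_part)
  kappa_of[layout$first_id] <- config$coupling
  kappa_of[layout$second_id] <- config$coupling
  for (item in names(.tlx_item_params)) {
    p <- .tlx_item_params[[item]]
    mu <- rep(p[["mean"]], n_part)
    if (item == "TD") {
      mu <- mu + config$tlx_temporal_effect * (kappa_of - 0.5) / 2
    }
    reports[[item]] <- pmin(10L, pmax(0L, as.integer(round(
      rnorm(n_part, mu, p[["sd"]])))))
  }

  structure(list(
    beats = beats,
    layout = layout,
    reports = reports,
    truth = list(coupling = config$coupling,
                 trend_participants = trend_participants,
                 disp_latent = disp_latent,
                 grid_t = grid_t),
    config = config
  ), class = "classroom")
}

#' @export
print.classroom <- function(x, ...) {
  nb <- lengths(x$beats)
  cat("Synthetic classroom: ", nrow(x$layout), " dyads (",
      length(x$beats), " participants), ",
      x$config$session_length_s, " s session\n", sep = "")
  cat("Beats per participant: ", min(nb), "-", max(nb),
      " (median ", round(median(nb)), ")\n", sep = "")
  cat("Dyad coupling kappa: ",
      paste(format(round(range(x$truth$coupling), 2)), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' Synthesize an ECG-like waveform from beat times
#'
#' Renders a sampled waveform with one dominant narrow positive
#' deflection (a QRS-like Gaussian template) centred at each beat time,
#' over low-amplitude Gaussian noise. Intended as a test substrate for
#' [detect_r_peaks()], not as physiologically realistic PQRST morphology.
#'
#' @param beat_times Strictly increasing beat times in seconds (may be
#'   empty, giving a noise-only trace).
#' @param sampling_rate Sampling rate in Hz (>= 100).
#' @param duration_s Trace duration; default covers the last beat + 0.5 s
#'   (minimum 1 s).
#' @param amplitude Peak amplitude of the QRS template, mV (default 1).
#' @param noise_sd Baseline noise SD, mV (default 0.02).
#' @param width_s Gaussian template SD in seconds (default 0.012, a
#'   narrow spike well inside a normal QRS duration).
#' @return List with `samples` (mV), `sampling_rate`, and `time_s`.
#' @examples
#' ecg <- synthesize_ecg(c(1, 2, 3), sampling_rate = 500)
#' peaks <- detect_r_peaks(ecg$samples, ecg$sampling_rate)
#' @export
synthesize_ecg <- function(beat_times, sampling_rate = 250,
                           duration_s = NULL, amplitude = 1,
                           noise_sd = 0.02, width_s = 0.012) {
  if (sampling_rate < 100) stop("sampling_rate must be >= 100 Hz")
  if (length(beat_times) && any(diff(beat_times) <= 0)) {
    stop("beat_times must be strictly increasing")
  }
  if (is.null(duration_s)) {
    duration_s <- if (length(beat_times)) max(beat_times) + 0.5 else 1
  }
  n <- ceiling(duration_s * sampling_rate) + 1L
  time_s <- (seq_len(n) - 1) / sampling_rate
  samples <- rnorm(n, 0, noise_sd)
  half <- ceiling(4 * width_s * sampling_rate)
  for (b in beat_times) {
    centre <- round(b * sampling_rate) + 1L
    idx <- max(1L, centre - half):min(n, centre + half)
    samples[idx] <- samples[idx] +
      amplitude * exp(-((time_s[idx] - b)^2) / (2 * width_s^2))
  }
  list(samples = samples, sampling_rate = sampling_rate, time_s = time_s)
}
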