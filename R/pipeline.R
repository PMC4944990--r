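#' Full compliance analysis of a classroom
#'
#' Runs the complete pipeline on a classroom — beat series to
#' artifact-filtered NN intervals, windowed HR/SDNN/rMSSD features over a
#' grid of window lengths, within-dyad compliance with its
#' class-restricted permutation test per (feature, window), and the
#' self-report regression for selected windows — and collects the results
#' in one object.
#'
#' @param classroom A [simulate_classroom()] result, or any list with
#'   `beats` (named list of beat times in seconds), `layout`
#'   (a [classroom_layout()]) and optionally `reports` (see
#'   [read_classroom()]).
#' @param window_lengths_s Window-length grid (default 60 to 300 s in
#'   40 s steps).
#' @param features HRV features to analyse.
#' @param n_permutations Null draws per test (default 10000).
#' @param seed Seed governing the permutation stream.
#' @param min_beats Minimum NN intervals per valid window.
#' @param origin_s Analysis start time (default 0: the baseline segment
#'   is included).
#' @param regress_windows_s Window lengths at which to fit the
#'   self-report regression (default `c(60, 300)`); ignored when
#'   `classroom$reports` is absent.
#' @param verbose Log per-stage counts to stderr.
#' @return An object of class `"spc_study"`: list with
#'   \describe{
#'     \item{tests}{named list (by window length) of [spc_test()] objects}
#'     \item{regressions}{named list `"<feature>_<window>"` of
#'       [spc_lm()] fits (when reports are available)}
#'     \item{counts}{per-participant data frame of beats, rejected
#'       intervals, and valid windows at the largest window length}
#'     \item{layout, call}{bookkeeping}
#'   }
#' @examples
#' cls <- simulate_classroom(classroom_config(
#'   n_dyads_per_class = c(3, 3), session_length_s = 1200, seed = 3))
#' st <- spc_study(cls, window_lengths_s = c(60, 300),
#'                 n_permutations = 200, seed = 1)
#' summary(st)
#' @export
spc_study <- function(classroom,
                      window_lengths_s = seq(60, 300, by = 40),
                      features = c("HR", "SDNN", "rMSSD"),
                      n_permutations = 10000L, seed = NULL,
                      min_beats = 10L, origin_s = 0,
                      regress_windows_s = c(60, 300),
                      verbose = FALSE) {
  if (is.null(classroom$layout) || nrow(classroom$layout) == 0L) {
    stop("classroom has an empty layout")
  }
  layout <- validate_layout(classroom$layout)
  if (any(window_lengths_s < 60)) {
    stop("window lengths below 60 s are unreliable for time-domain HRV")
  }
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  ids <- as.character(c(layout$first_id, layout$second_id))
  missing_ids <- setdiff(ids, names(classroom$beats))
  if (length(missing_ids)) {
    stop("layout references participant(s) with no recording: ",
         paste(missing_ids, collapse = ", "))
  }
  log_msg <- function(...) if (verbose) message("[spc_study] ", ...)

  nn_list <- setNames(lapply(ids, function(id) {
    beats_to_nn(classroom$beats[[id]], participant_id = as.integer(id))
  }), ids)
  log_msg("NN series: ",
          paste0(range(vapply(nn_list, nrow, integer(1))), collapse = "-"),
          " intervals/participant, ",
          sum(vapply(nn_list, attr, integer(1), "rejected_count")),
          " intervals rejected in total")

  if (!is.null(seed)) set.seed(seed)
  tests <- setNames(vector("list", length(window_lengths_s)),
                    as.character(window_lengths_s))
  fsets_by_len <- tests
  for (len in window_lengths_s) {
    spec <- window_spec(len, origin_s = origin_s)
    fsets <- features_by_participant(nn_list, spec, min_beats = min_beats)
    fsets_by_len[[as.character(len)]] <- fsets
    tests[[as.character(len)]] <- spc_test(
      fsets, layout, features = features,
      n_permutations = n_permutations, keep_samples = FALSE)
    tab <- tests[[as.character(len)]]$table
    log_msg("window ", len, " s: mu_true = ",
            paste0(tab$feature, " ", round(tab$mu_true, 3), collapse = ", "))
  }

  regressions <- list()
  if (!is.null(classroom$reports) && nrow(layout) < 8L) {
    log_msg("fewer than 8 dyads: self-report regression skipped")
  } else if (!is.null(classroom$reports)) {
    sums <- dyad_sums(classroom$reports, layout)
    for (len in intersect(regress_windows_s, window_lengths_s)) {
      for (f in features) {
        comp <- tests[[as.character(len)]]$compliance[[f]]
        regressions[[paste0(f, "_", len)]] <- spc_lm(sums, comp)
      }
    }
  }

  counts <- data.frame(
    participant_id = as.integer(ids),
    n_beats = lengths(classroom$beats[ids]),
    n_rejected = vapply(nn_list, attr, integer(1), "rejected_count"),
    n_valid_windows = vapply(
      fsets_by_len[[as.character(max(window_lengths_s))]],
      function(f) sum(f$valid), integer(1)),
    row.names = NULL
  )

  structure(list(tests = tests, regressions = regressions,
                 counts = counts, layout = layout,
                 n_permutations = n_permutations, seed = seed,
                 call = match.call()),
            class = "spc_study")
}

#' @export
print.spc_study <- function(x, digits = 3, ...) {
  cat("Compliance study: ", nrow(x$layout), " dyads, windows ",
      paste(names(x$tests), collapse = "/"), " s, ",
      x$n_permutations, " permutations\n\n", sep = "")
  print(summary(x), digits = digits)
  if (length(x$regressions)) {
    cat("\nSelf-report regressions (adjusted R-squared):\n")
    for (nm in names(x$regressions)) {
      cat("  ", nm, ": ", round(x$regressions[[nm]]$adj_r2, digits),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
summary.spc_study <- function(object, ...) {
  out <- do.call(rbind, lapply(object$tests, summary))
  rownames(out) <- NULL
  out
}
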