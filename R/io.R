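#' Read a single-channel ECG CSV
#'
#' Expects a header `time_s,mv` and numeric columns. Malformed cells are
#' reported with their line number.
#'
#' @param path File path.
#' @return Data frame `time_s`, `mv`.
#' @export
read_ecg_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path, colClasses = "character")
  need <- c("time_s", "mv")
  if (!all(need %in% names(d))) {
    stop(path, ": expected columns time_s,mv; found ",
         paste(names(d), collapse = ","))
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & nzchar(d[[col]]))
    if (length(bad) || anyNA(v)) {
      line <- if (length(bad)) bad[1L] else which(is.na(v))[1L]
      stop(path, ": non-numeric value in column '", col,
           "' at line ", line + 1L)   # +1 for the header row
    }
    d[[col]] <- v
  }
  d
}

#' @rdname read_ecg_csv
#' @param ecg List with `samples`, `sampling_rate` (see
#'   [synthesize_ecg()]), or a data frame `time_s`, `mv`.
#' @export
write_ecg_csv <- function(ecg, path) {
  d <- if (is.data.frame(ecg)) ecg else
    data.frame(time_s = ecg$time_s, mv = ecg$samples)
  write.csv(d[, c("time_s", "mv")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a classroom layout CSV
#'
#' Columns: `dyad_id, first_id, second_id, class_id`.
#'
#' @param path File path.
#' @return A [classroom_layout()].
#' @export
read_layout_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path)
  need <- c("dyad_id", "first_id", "second_id", "class_id")
  if (!all(need %in% names(d))) {
    stop(path, ": expected columns ", paste(need, collapse = ","))
  }
  classroom_layout(d$first_id, d$second_id, d$class_id, dyad_id = d$dyad_id)
}

#' @rdname read_layout_csv
#' @param layout A [classroom_layout()].
#' @export
write_layout_csv <- function(layout, path) {
  write.csv(as.data.frame(validate_layout(layout)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write self-report CSVs
#'
#' Columns: `participant_id, MD, TD, Pe, Ef, Fr, Na` (integers 0-10).
#'
#' @param path File path.
#' @return Data frame of reports.
#' @export
read_reports_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path)
  need <- c("participant_id", "MD", "TD", "Pe", "Ef", "Fr", "Na")
  if (!all(need %in% names(d))) {
    stop(path, ": expected columns ", paste(need, collapse = ","))
  }
  d
}

#' @rdname read_reports_csv
#' @param reports Data frame of reports.
#' @export
write_reports_csv <- function(reports, path) {
  write.csv(reports, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read NN-interval TSVs
#'
#' Long format, one row per accepted interval:
#' `participant_id, time_s, nn_ms`.
#'
#' @param nn_list Named list of `nn_series`.
#' @param path File path.
#' @export
write_nn_tsv <- function(nn_list, path) {
  rows <- lapply(names(nn_list), function(id) {
    nn <- nn_list[[id]]
    if (!nrow(nn)) return(NULL)
    data.frame(participant_id = as.integer(id),
               time_s = nn$time_s, nn_ms = nn$nn_ms)
  })
  write.table(do.call(rbind, rows), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nn_tsv
#' @return For the reader: a named list of `nn_series` (adjacency is
#'   reconstructed from row order within participant).
#' @export
read_nn_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path)
  need <- c("participant_id", "time_s", "nn_ms")
  if (!all(need %in% names(d))) {
    stop(path, ": expected columns ", paste(need, collapse = "\t"))
  }
  out <- lapply(split(d, d$participant_id), function(p) {
    nn <- data.frame(time_s = p$time_s, nn_ms = p$nn_ms,
                     raw_index = seq_len(nrow(p)))
    attr(nn, "rejected_count") <- NA_integer_
    attr(nn, "participant_id") <- p$participant_id[1L]
    class(nn) <- c("nn_series", "data.frame")
    nn
  })
  out[order(as.integer(names(out)))]
}

#' Write a synthetic classroom to disk
#'
#' Writes the same on-disk formats the pipeline reads — per-participant
#' beat or ECG CSVs, a layout CSV, a reports CSV and a session annotation
#' CSV — so simulated classrooms feed the file-based entry point
#' unchanged.
#'
#' @param classroom A [simulate_classroom()] result.
#' @param dir Output directory (created if needed).
#' @param ecg_sampling_rate If non-`NULL`, render each participant's
#'   beats to a waveform CSV `ecg_<id>.csv` at this rate; otherwise write
#'   beat-time CSVs `beats_<id>.csv` (column `time_s`).
#' @param baseline_s Length of the baseline segment in the annotation
#'   file (default 420 s, a 7 minute baseline video).
#' @return The directory, invisibly.
#' @export
write_classroom <- function(classroom, dir, ecg_sampling_rate = NULL,
                            baseline_s = 420) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_layout_csv(classroom$layout, file.path(dir, "layout.csv"))
  write_reports_csv(classroom$reports, file.path(dir, "reports.csv"))
  ann <- data.frame(
    segment = c("baseline", "driving"),
    start_s = c(0, baseline_s),
    end_s = c(baseline_s, classroom$config$session_length_s)
  )
  write.csv(ann, file.path(dir, "annotations.csv"),
            row.names = FALSE, quote = FALSE)
  for (id in names(classroom$beats)) {
    if (is.null(ecg_sampling_rate)) {
      write.csv(data.frame(time_s = classroom$beats[[id]]),
                file.path(dir, paste0("beats_", id, ".csv")),
                row.names = FALSE, quote = FALSE)
    } else {
      write_ecg_csv(synthesize_ecg(classroom$beats[[id]],
                                   ecg_sampling_rate),
                    file.path(dir, paste0("ecg_", id, ".csv")))
    }
  }
  invisible(dir)
}

#' Read classroom inputs from disk
#'
#' Counterpart of [write_classroom()]: reads the layout, reports, and
#' per-participant beat CSVs (`beats_<id>.csv`) or ECG CSVs
#' (`ecg_<id>.csv`, run through [detect_r_peaks()]).
#'
#' @param dir Input directory.
#' @param sampling_rate Sampling rate of ECG CSVs, required when reading
#'   waveforms.
#' @return List with `beats` (named list of beat times), `layout`,
#'   `reports`.
#' @export
read_classroom <- function(dir, sampling_rate = NULL) {
  layout <- read_layout_csv(file.path(dir, "layout.csv"))
  reports <- read_reports_csv(file.path(dir, "reports.csv"))
  ids <- c(layout$first_id, layout$second_id)
  beats <- setNames(vector("list", length(ids)), as.character(ids))
  for (id in as.character(ids)) {
    bf <- file.path(dir, paste0("beats_", id, ".csv"))
    ef <- file.path(dir, paste0("ecg_", id, ".csv"))
    if (file.exists(bf)) {
      beats[[id]] <- read.csv(bf)$time_s
    } else if (file.exists(ef)) {
      ecg <- read_ecg_csv(ef)
      fs <- sampling_rate %||%
        round(1 / median(diff(ecg$time_s)))
      beats[[id]] <- detect_r_peaks(ecg$mv, fs)
    } else {
      stop("no beat or ECG file for participant ", id, " in ", dir)
    }
  }
  list(beats = beats, layout = layout, reports = reports)
}

#' The published classroom field study: dyad sums and correlations
#'
#' Per-dyad data from a published classroom pair-programming field study
#' of 19 collaborating dyads (38 participants, four classes): the dyad
#' sums of six self-report items (NASA-TLX items plus a
#' navigating-concentration item, each member scoring 0-10) and the
#' within-dyad Pearson correlations of windowed HR, SDNN and rMSSD at 60 s
#' and 300 s window lengths. These printed values allow the compliance
#' mean, instrument means, and the self-report regression to be
#' recomputed without the raw ECG recordings.
#'
#' @return Data frame with columns `dyad_id`, `sex` (MM/FF/MF), the item
#'   sums `MD`, `TD`, `Pe`, `Ef`, `Fr`, `Na` (0-20), and correlations
#'   `HR_60`, `SDNN_60`, `rMSSD_60`, `HR_300`, `SDNN_300`, `rMSSD_300`.
#' @examples
#' d <- study_dyads()
#' mean_dyad_correlation(d$SDNN_300)$mu    # 0.290
#' @export
study_dyads <- function() {
  path <- system.file("extdata", "classroom_study_dyads.csv",
                      package = "dyadsync", mustWork = TRUE)
  read.csv(path)
}
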