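trials_schema <- c("subject_id", "group", "tempo_bpm", "trial_index",
                   "event_index", "time_s")

#' Read movement trials from a long-format table
#'
#' Reads a UTF-8 comma-separated table with one row per movement event and
#' columns `subject_id, group, tempo_bpm, trial_index, event_index, time_s`,
#' and returns one [movement_trial()] per (subject, tempo, trial) combination.
#' This is the documented export format for trial-by-trial spreadsheet data:
#' export each subject's events as rows of event index and low-point time in
#' seconds, with the first beat onset of each trial at time zero.
#'
#' @param path Path to the CSV file.
#' @return List of `movement_trial` objects, ordered by subject, tempo, trial.
#' @details Row order within a trial is fixed by `event_index`, and duplicate
#'   (subject, tempo, trial, event_index) rows or non-increasing event times
#'   are validation errors naming the offending trial.
#' @seealso [trials_to_table()], [write_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  trials_from_table(tbl)
}

#' Build movement trials from an in-memory event table
#'
#' @param tbl Data frame with the columns listed under [read_trials()].
#' @return List of `movement_trial` objects.
#' @export
trials_from_table <- function(tbl) {
  missing_cols <- setdiff(trials_schema, names(tbl))
  if (length(missing_cols)) {
    stop("trials table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- dplyr::arrange(tbl, .data$subject_id, .data$tempo_bpm,
                        .data$trial_index, .data$event_index)
  key <- paste(tbl$subject_id, tbl$tempo_bpm, tbl$trial_index, sep = "\r")
  dup <- duplicated(paste(key, tbl$event_index, sep = "\r"))
  if (any(dup)) {
    bad <- tbl[which(dup)[1], ]
    stop(sprintf(
      "duplicate event_index %d in trial %s/%g bpm/#%d",
      bad$event_index, bad$subject_id, bad$tempo_bpm, bad$trial_index),
      call. = FALSE)
  }
  lapply(split(tbl, factor(key, levels = unique(key))), function(d) {
    movement_trial(d$subject_id[1], d$group[1], d$tempo_bpm[1],
                   d$trial_index[1], d$time_s)
  }) |> unname()
}

#' Flatten movement trials to the long event table
#'
#' Inverse of [trials_from_table()]: one row per event, columns in the
#' canonical schema.
#'
#' @param trials List of `movement_trial` objects.
#' @return A tibble.
#' @export
trials_to_table <- function(trials) {
  stopifnot(length(trials) >= 1L)
  dplyr::bind_rows(lapply(trials, function(tr) {
    tibble::tibble(
      subject_id = tr$subject_id,
      group = tr$group,
      tempo_bpm = tr$tempo_bpm,
      trial_index = tr$trial_index,
      event_index = seq_along(tr$event_times_s),
      time_s = tr$event_times_s
    )
  }))
}

#' Write movement trials to CSV
#'
#' @param trials List of `movement_trial` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials_to_table(trials), path, progress = FALSE)
  invisible(path)
}

# Columns holding angles: written with an explicit sign so the convention
# (negative = movement before the beat) is visible in the file itself.
angle_cols <- c("mean_phase_deg", "circ_sd_deg")

#' Write summary tables to CSV at fixed precision
#'
#' Writes per-trial or per-subject summary rows as CSV, numeric columns
#' formatted to 6 decimal places (angles with an explicit leading sign), so
#' the table round-trips bit-exactly through [read_summaries()] at that
#' precision.
#'
#' @param summaries Non-empty data frame of summaries ([summarize_trial()] or
#'   [summarize_subject()] rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  if (is.null(summaries) || !nrow(summaries)) {
    stop("refusing to write an empty summary table", call. = FALSE)
  }
  out <- summaries
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      fmt <- if (nm %in% angle_cols) "%+.6f" else "%.6f"
      out[[nm]] <- sprintf(fmt, out[[nm]])
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a summary table written by [write_summaries()]
#'
#' @param path Path to the CSV file.
#' @return A tibble with numeric columns restored.
#' @export
read_summaries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
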