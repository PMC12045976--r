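#' Relative phases and intervals for one trial
#'
#' Matches each movement event to its nearest metronome beat and expresses the
#' timing error as a phase angle in degrees of the beat cycle:
#' `phase = 360 * (t_event - t_beat) / period` under the default sign
#' convention, so an event just before its beat — the classic negative mean
#' asynchrony — has a small negative phase. Phases are wrapped to
#' (-180, 180].
#'
#' @param trial A [movement_trial()].
#' @param grid A [make_beat_grid()] for the trial's stimulus.
#' @param cfg An [analysis_config()]; controls the sign convention and the
#'   tie-break when an event is exactly half a period from two beats.
#' @return An object of class `phase_series`: list with `phases_deg`,
#'   `beat_index` (1-based matched onset, non-decreasing), `intervals_s`
#'   (successive differences of the matched event times), `event_times_s`,
#'   and `n_unmatched` (events falling more than half a period outside the
#'   grid, excluded with a message).
#' @export
compute_phase_series <- function(trial, grid, cfg = analysis_config()) {
  stopifnot(inherits(trial, "movement_trial"), inherits(grid, "beat_grid"))
  times <- trial$event_times_s
  if (!length(times)) stop("trial has no events", call. = FALSE)
  onsets <- grid$onsets_s
  period <- grid$period_s
  half <- period / 2
  in_span <- times >= onsets[1] - half & times <= onsets[length(onsets)] + half
  n_unmatched <- sum(!in_span)
  if (n_unmatched > 0) {
    message(sprintf(
      "trial %s/%g bpm/#%d: %d event(s) beyond the beat grid excluded",
      trial$subject_id, trial$tempo_bpm, trial$trial_index, n_unmatched))
  }
  times <- times[in_span]
  if (!length(times)) stop("no events fall within the beat grid", call. = FALSE)

  # nearest onset; exact half-period ties broken per cfg$nearest_beat_tie
  k_lo <- pmin(pmax(floor((times - onsets[1]) / period) + 1, 1L),
               length(onsets))
  k_hi <- pmin(k_lo + 1L, length(onsets))
  d_lo <- abs(times - onsets[k_lo])
  d_hi <- abs(times - onsets[k_hi])
  tol <- 1e-9 * period
  pick_lo <- if (cfg$nearest_beat_tie == "earlier") d_lo <= d_hi + tol
             else d_lo < d_hi - tol
  beat_index <- ifelse(pick_lo, k_lo, k_hi)

  phase <- 360 * (times - onsets[beat_index]) / period
  if (cfg$phase_sign == "beat_minus_movement") phase <- -phase
  structure(
    list(
      phases_deg = wrap_deg(phase),
      beat_index = as.integer(beat_index),
      intervals_s = diff(times),
      event_times_s = times,
      n_unmatched = n_unmatched
    ),
    class = "phase_series"
  )
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d events, mean phase %.1f deg, R = %.3f\n",
              length(x$phases_deg), circular_mean(x$phases_deg),
              vector_length(x$phases_deg)))
  invisible(x)
}

performed_tempo <- function(intervals_s, method) {
  inst_bpm <- 60 / intervals_s
  if (method == "mean_of_instantaneous_bpm") {
    c(mean = mean(inst_bpm), sd = stats::sd(inst_bpm))
  } else {
    c(mean = 60 / mean(intervals_s), sd = stats::sd(inst_bpm))
  }
}

#' Per-trial circular and interval summary
#'
#' Computes the descriptives reported per stimulus exposure: mean and SD of
#' the inter-event intervals, performed tempo in bpm (by default the mean of
#' the instantaneous 60/interval values), circular mean phase, mean resultant
#' vector length and the derived circular SD.
#'
#' @inheritParams compute_phase_series
#' @return One-row tibble with columns `subject_id, group, tempo_bpm,
#'   trial_index, n_events, mean_interval_s, sd_interval_s,
#'   performed_tempo_bpm, sd_tempo_bpm, mean_phase_deg, vector_length,
#'   circ_sd_deg`.
#' @export
summarize_trial <- function(trial, grid, cfg = analysis_config()) {
  ps <- compute_phase_series(trial, grid, cfg)
  if (length(ps$event_times_s) < 2L) {
    stop("summarize_trial() needs at least 2 matched events", call. = FALSE)
  }
  tempo <- performed_tempo(ps$intervals_s, cfg$tempo_method)
  r <- vector_length(ps$phases_deg)
  tibble::tibble(
    subject_id = trial$subject_id,
    group = trial$group,
    tempo_bpm = trial$tempo_bpm,
    trial_index = trial$trial_index,
    n_events = length(ps$phases_deg),
    mean_interval_s = mean(ps$intervals_s),
    sd_interval_s = if (length(ps$intervals_s) > 1) stats::sd(ps$intervals_s) else 0,
    performed_tempo_bpm = unname(tempo["mean"]),
    sd_tempo_bpm = if (length(ps$intervals_s) > 1) unname(tempo["sd"]) else 0,
    mean_phase_deg = circular_mean(ps$phases_deg),
    vector_length = r,
    circ_sd_deg = if (r > 0) circ_sd_deg(r) else NA_real_
  )
}

#' Subject-by-tempo aggregate summary
#'
#' Aggregates one subject's trials at one tempo the way per-subject rows are
#' conventionally tabulated: tempo and vector length as linear averages of
#' the trial means, tempo SD as the SD over all intervals pooled across the
#' trials (on the instantaneous-bpm scale), and the mean phase as the
#' circular average of the trial mean phases.
#'
#' @param trials List of [movement_trial()] objects, all from one subject at
#'   one tempo.
#' @param grid A [make_beat_grid()] shared by the trials (or a list of grids,
#'   one per trial).
#' @param cfg An [analysis_config()].
#' @return One-row tibble with columns `subject_id, group, tempo_bpm,
#'   n_trials, mean_tempo_bpm, sd_tempo_bpm, mean_phase_deg,
#'   mean_vector_length`.
#' @export
summarize_subject <- function(trials, grid, cfg = analysis_config()) {
  stopifnot(length(trials) >= 1L)
  grids <- if (inherits(grid, "beat_grid")) rep(list(grid), length(trials))
           else grid
  stopifnot(length(grids) == length(trials))
  ids <- vapply(trials, `[[`, "", "subject_id")
  tempos <- vapply(trials, `[[`, 0, "tempo_bpm")
  if (length(unique(ids)) != 1L || length(unique(tempos)) != 1L) {
    stop("summarize_subject() requires trials of a single subject at a single tempo",
         call. = FALSE)
  }
  per_trial <- dplyr::bind_rows(
    Map(summarize_trial, trials, grids, MoreArgs = list(cfg = cfg)))
  pooled_intervals <- unlist(lapply(seq_along(trials), function(i) {
    compute_phase_series(trials[[i]], grids[[i]], cfg)$intervals_s
  }))
  tibble::tibble(
    subject_id = ids[1],
    group = trials[[1]]$group,
    tempo_bpm = tempos[1],
    n_trials = length(trials),
    mean_tempo_bpm = mean(per_trial$performed_tempo_bpm),
    sd_tempo_bpm = stats::sd(60 / pooled_intervals),
    mean_phase_deg = circular_mean(per_trial$mean_phase_deg),
    mean_vector_length = mean(per_trial$vector_length)
  )
}

#' Summarize every trial of a study
#'
#' Convenience driver: builds a beat grid per tempo (first onset at time
#' zero) and returns the per-trial summary table for all trials, plus the
#' subject-by-tempo aggregates.
#'
#' @param trials List of [movement_trial()] objects.
#' @param cfg An [analysis_config()].
#' @param n_beats Number of beats per stimulus presentation (grid length).
#' @return List with tibbles `trial_summaries` and `subject_summaries`.
#' @export
summarize_study <- function(trials, cfg = analysis_config(), n_beats = 25) {
  stopifnot(length(trials) >= 1L)
  grids <- lapply(trials, function(tr) make_beat_grid(tr$tempo_bpm, n_beats))
  trial_summaries <- dplyr::bind_rows(
    Map(summarize_trial, trials, grids, MoreArgs = list(cfg = cfg)))
  keys <- vapply(trials, function(tr)
    paste(tr$subject_id, tr$tempo_bpm, sep = "\r"), "")
  subject_summaries <- dplyr::bind_rows(lapply(
    split(seq_along(trials), factor(keys, levels = unique(keys))),
    function(idx) summarize_subject(trials[idx],
                                    grids[idx], cfg)))
  list(trial_summaries = trial_summaries,
       subject_summaries = dplyr::arrange(subject_summaries,
                                          .data$subject_id, .data$tempo_bpm))
}
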