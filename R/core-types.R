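#' Construct a metronome beat grid
#'
#' An isochronous grid of beat onsets: `n_beats` onsets starting at `t0`,
#' spaced `60 / tempo_bpm` seconds apart. The default origin `t0 = 0` places
#' the first beat onset at time zero, the reference frame used by both the
#' analysis and the trial simulator.
#'
#' @param tempo_bpm Stimulus tempo in beats per minute (> 0).
#' @param n_beats Number of beat onsets (>= 1).
#' @param t0 Time of the first onset, seconds.
#' @return An object of class `beat_grid`: a list with `tempo_bpm`,
#'   `period_s` (= 60 / tempo_bpm) and `onsets_s` (strictly increasing).
#' @examples
#' make_beat_grid(120, 3) # onsets 0, 0.5, 1
#' @export
make_beat_grid <- function(tempo_bpm, n_beats, t0 = 0) {
  if (!is.numeric(tempo_bpm) || length(tempo_bpm) != 1L || tempo_bpm <= 0) {
    stop("tempo_bpm must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 1 ||
      n_beats != round(n_beats)) {
    stop("n_beats must be a positive integer", call. = FALSE)
  }
  period <- 60 / tempo_bpm
  structure(
    list(
      tempo_bpm = tempo_bpm,
      period_s = period,
      onsets_s = t0 + (seq_len(n_beats) - 1) * period
    ),
    class = "beat_grid"
  )
}

#' @export
print.beat_grid <- function(x, ...) {
  cat(sprintf("<beat_grid> %g bpm, %d onsets from %.4f s (period %.4f s)\n",
              x$tempo_bpm, length(x$onsets_s), x$onsets_s[1], x$period_s))
  invisible(x)
}

trial_groups <- c("sea_lion", "human", "simulated", "synthetic")

#' Construct a movement trial
#'
#' One subject's timed movement events (head-bob or arm-chop nadirs) for one
#' stimulus exposure. Event times are the seconds at which each movement
#' reached its low point, in the same clock as the beat grid.
#'
#' @param subject_id Subject identifier (single string).
#' @param group One of `"sea_lion"`, `"human"`, `"simulated"`, `"synthetic"`.
#' @param tempo_bpm Stimulus tempo of the exposure.
#' @param trial_index Positive integer index of the exposure within the
#'   subject-by-tempo series.
#' @param event_times_s Strictly increasing numeric vector of event times in
#'   seconds.
#' @return An object of class `movement_trial`.
#' @export
movement_trial <- function(subject_id, group, tempo_bpm, trial_index,
                           event_times_s) {
  group <- match.arg(group, trial_groups)
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.numeric(tempo_bpm), length(tempo_bpm) == 1L, tempo_bpm > 0,
            is.numeric(trial_index), length(trial_index) == 1L,
            trial_index >= 1, trial_index == round(trial_index))
  event_times_s <- as.numeric(event_times_s)
  if (length(event_times_s) < 1L || any(diff(event_times_s) <= 0)) {
    stop(sprintf(
      "trial %s/%g bpm/#%d: event times must be non-empty and strictly increasing",
      subject_id, tempo_bpm, trial_index), call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, group = group, tempo_bpm = tempo_bpm,
         trial_index = as.integer(trial_index),
         event_times_s = event_times_s),
    class = "movement_trial"
  )
}

#' @export
print.movement_trial <- function(x, ...) {
  cat(sprintf("<movement_trial> %s (%s), %g bpm, trial %d, %d events\n",
              x$subject_id, x$group, x$tempo_bpm, x$trial_index,
              length(x$event_times_s)))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the conventions of the phase analysis. The defaults encode the
#' package's standing choices:
#' * `phase_sign = "movement_minus_beat"`: a movement preceding its beat has a
#'   negative phase, so negative mean asynchrony appears as a negative angle.
#'   `"beat_minus_movement"` flips the sign of every phase.
#' * `nearest_beat_tie = "earlier"`: an event exactly half a period between
#'   two beats is assigned to the earlier one.
#' * `tempo_method = "mean_of_instantaneous_bpm"`: the performed tempo of a
#'   trial is the mean of 60/interval over its inter-event intervals (and its
#'   SD the SD of those instantaneous bpm values);
#'   `"reciprocal_of_mean_interval"` uses 60/mean(interval) instead.
#'
#' @param phase_sign Phase sign convention.
#' @param nearest_beat_tie Tie-break for events equidistant from two beats.
#' @param tempo_method How per-trial performed tempo is computed.
#' @param alpha Significance level for downstream tests, in (0, 1).
#' @param rng_seed Optional integer seed recorded for provenance.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(phase_sign = c("movement_minus_beat",
                                           "beat_minus_movement"),
                            nearest_beat_tie = c("earlier", "later"),
                            tempo_method = c("mean_of_instantaneous_bpm",
                                             "reciprocal_of_mean_interval"),
                            alpha = 0.05,
                            rng_seed = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  structure(
    list(
      phase_sign = match.arg(phase_sign),
      nearest_beat_tie = match.arg(nearest_beat_tie),
      tempo_method = match.arg(tempo_method),
      alpha = alpha,
      rng_seed = rng_seed
    ),
    class = "analysis_config"
  )
}
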