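rank_metrics <- c("tempo_error_bpm", "sd_tempo_bpm", "abs_phase_deg",
                  "vector_length")

#' Rank a focal subject against comparator subjects
#'
#' For each performance metric at one tempo, counts how many comparators the
#' focal subject beats, where "beats" means being strictly closer to perfect
#' performance: tempo error 0 (performed mean tempo equal to the stimulus),
#' pooled interval SD 0, mean phase 0 and vector length 1. Ties are
#' conservative: a tied comparator is not counted as beaten.
#'
#' @param focal One-row subject-by-tempo summary ([summarize_subject()]).
#' @param comparators Subject-by-tempo summary tibble of the comparison
#'   group, all at the same tempo as `focal`.
#' @param tempo_bpm The stimulus tempo; all rows must match it.
#' @return Tibble with one row per metric: `metric, focal_value,
#'   focal_distance, n_beaten, n_comparators`.
#' @export
rank_against_humans <- function(focal, comparators, tempo_bpm) {
  stopifnot(is.data.frame(focal), nrow(focal) == 1L,
            is.data.frame(comparators), nrow(comparators) >= 1L)
  if (any(c(focal$tempo_bpm, comparators$tempo_bpm) != tempo_bpm)) {
    stop("all summaries must be at tempo ", tempo_bpm, " bpm", call. = FALSE)
  }
  distance <- function(df, metric) {
    switch(metric,
      tempo_error_bpm = abs(df$mean_tempo_bpm - tempo_bpm),
      sd_tempo_bpm = abs(df$sd_tempo_bpm),
      abs_phase_deg = abs(wrap_deg(df$mean_phase_deg)),
      vector_length = abs(1 - df$mean_vector_length)
    )
  }
  value <- function(df, metric) {
    switch(metric,
      tempo_error_bpm = df$mean_tempo_bpm,
      sd_tempo_bpm = df$sd_tempo_bpm,
      abs_phase_deg = df$mean_phase_deg,
      vector_length = df$mean_vector_length
    )
  }
  dplyr::bind_rows(lapply(rank_metrics, function(m) {
    d_focal <- distance(focal, m)
    d_comp <- distance(comparators, m)
    tibble::tibble(
      metric = m,
      focal_value = value(focal, m),
      focal_distance = d_focal,
      n_beaten = sum(d_comp > d_focal),
      n_comparators = length(d_comp)
    )
  }))
}

#' First-versus-last trial learning check
#'
#' Compares the raw phases of a subject's first and last exposures at one
#' tempo with a Watson-Williams test; a significant difference in mean
#' direction across the session indicates a learning (or drift) effect.
#'
#' @param phases_by_trial List of numeric phase vectors, one per trial, in
#'   trial order (at least 2 trials).
#' @return A `circ_test` from [watson_williams()] on the first and last
#'   elements.
#' @export
first_vs_last_trial <- function(phases_by_trial) {
  if (!is.list(phases_by_trial) || length(phases_by_trial) < 2L) {
    stop("need at least 2 trials to compare first vs last", call. = FALSE)
  }
  watson_williams(list(
    phases_by_trial[[1]],
    phases_by_trial[[length(phases_by_trial)]]
  ))
}

#' Within-trial half comparison
#'
#' Pools the first `n_lead` phases and the last `n_trail` phases of each
#' trial (for a 25-event trial with the default 12/12 split, chops 1-12
#' versus 14-25; the middle chop belongs to neither half) and compares the
#' two pools with a Watson-Williams test. Also reports the signed circular
#' mean difference, second half minus first half, so a drift toward more
#' negative phase late in trials appears as a negative difference.
#'
#' @param phases_by_trial List of numeric phase vectors, one per trial.
#' @param n_lead,n_trail Number of leading/trailing phases per trial.
#' @return A `circ_test` with extra components `mean_diff_deg`,
#'   `n_trials_used` and `n_trials_excluded`. Trials shorter than
#'   `max(n_lead, n_trail) + 1` events are excluded with a warning; if all
#'   are excluded, an error.
#' @export
within_trial_halves <- function(phases_by_trial, n_lead = 12, n_trail = 12) {
  stopifnot(is.list(phases_by_trial), length(phases_by_trial) >= 1L)
  min_len <- max(n_lead, n_trail) + 1L
  usable <- vapply(phases_by_trial, function(p) length(p) >= min_len, TRUE)
  if (any(!usable)) {
    warning(sum(!usable), " trial(s) shorter than ", min_len,
            " events excluded from the halves comparison", call. = FALSE)
  }
  if (!any(usable)) {
    stop("no trial long enough for the halves comparison", call. = FALSE)
  }
  kept <- phases_by_trial[usable]
  lead <- unlist(lapply(kept, function(p) p[seq_len(n_lead)]))
  trail <- unlist(lapply(kept, function(p) {
    p[(length(p) - n_trail + 1L):length(p)]
  }))
  res <- watson_williams(list(lead, trail))
  res$mean_diff_deg <- wrap_deg(circular_mean(trail) - circular_mean(lead))
  res$n_trials_used <- length(kept)
  res$n_trials_excluded <- sum(!usable)
  res
}

#' Compare one subject's phases to a group at the same tempo
#'
#' Two-group Watson-Williams test of the subject's raw trial phases against
#' the pooled group phases at the same tempo.
#'
#' @param subject_phases_deg Numeric vector of the subject's phases.
#' @param group_phases_deg Numeric vector of the comparison group's phases.
#' @return A `circ_test`.
#' @export
subject_vs_group_phase <- function(subject_phases_deg, group_phases_deg) {
  watson_williams(list(subject_phases_deg, group_phases_deg))
}
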