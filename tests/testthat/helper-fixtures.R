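# Shared fixture builders. Everything is generated in code; no data files.

# A trial whose events sit at a constant offset (seconds) from every beat of
# a tempo_bpm grid with first onset at 0.
offset_trial <- function(offset_s, tempo_bpm = 120, n_beats = 25,
                         subject_id = "s1", group = "human",
                         trial_index = 1) {
  period <- 60 / tempo_bpm
  movement_trial(subject_id, group, tempo_bpm, trial_index,
                 (seq_len(n_beats) - 1) * period + offset_s)
}

# Long-format event table for a couple of interleaved subjects.
two_subject_table <- function() {
  tibble::tibble(
    subject_id = c("a", "b", "a", "b", "a", "b"),
    group = "human",
    tempo_bpm = 120,
    trial_index = 1L,
    event_index = c(1L, 1L, 2L, 2L, 3L, 3L),
    time_s = c(0.1, 0.05, 0.6, 0.55, 1.1, 1.05)
  )
}

# Degenerate window models: every window emits interval = period exactly and
# a near-point-mass phase at mu.
degenerate_models <- function(n_windows = 22, period_s = 0.5, mu_deg = 0,
                              kappa = 1e5) {
  tibble::tibble(
    window_index = seq_len(n_windows),
    interval_mu_s = period_s,
    interval_sigma_s = 0,
    phase_mu_deg = mu_deg,
    phase_kappa = kappa,
    n_phase_obs = 10L,
    n_interval_obs = 10L
  )
}

# Phase series built directly (bypassing event matching) for window-fit tests.
manual_phase_series <- function(phases_deg, intervals_s) {
  structure(
    list(phases_deg = phases_deg, beat_index = seq_along(phases_deg),
         intervals_s = intervals_s,
         event_times_s = cumsum(c(0, intervals_s)),
         n_unmatched = 0L),
    class = "phase_series"
  )
}

# Phase series for every trial of a study, via the standard pipeline.
study_phase_series <- function(trials, n_beats = 25,
                               cfg = analysis_config()) {
  lapply(trials, function(tr) {
    compute_phase_series(tr, make_beat_grid(tr$tempo_bpm, n_beats), cfg)
  })
}
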