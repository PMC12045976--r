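# Brute-force complex-sum oracle for circular descriptives.
oracle_mean <- function(ph) {
  z <- mean(exp(1i * ph * pi / 180))
  Arg(z) * 180 / pi
}
oracle_r <- function(ph) Mod(mean(exp(1i * ph * pi / 180)))

test_that("circular mean and vector length match the complex-sum oracle", {
  expect_equal(circular_mean(c(30, -30)), 0)
  expect_equal(circular_mean(c(170, -170)), 180) # wraps, not 0
  expect_equal(circular_mean(c(10, 20, 30)), oracle_mean(c(10, 20, 30)))
  expect_equal(vector_length(rep(42, 7)), 1)
  expect_equal(vector_length(c(0, 90, 180, 270)), 0, tolerance = 1e-12)
  expect_equal(vector_length(c(30, -30)), cos(pi / 6))

  set.seed(101)
  for (i in 1:50) {
    ph <- runif(sample(3:40, 1), -720, 720)
    expect_equal(circular_mean(ph), wrap_deg(oracle_mean(ph)),
                 tolerance = 1e-9)
    expect_equal(vector_length(ph), oracle_r(ph), tolerance = 1e-9)
  }

  expect_error(circular_mean(numeric(0)), "at least one")
  expect_error(circular_mean(c(90, -90)), "undefined")
  expect_error(vector_length(numeric(0)), "at least one")
})

test_that("phase computation follows the sign convention and matching rules", {
  cfg <- analysis_config()
  grid <- make_beat_grid(120, 25)

  # event 0.1 s before its beat at 0.5 s period: 0.1/0.5 * 360 = 72 deg early
  tr <- movement_trial("s", "human", 120, 1, c(9.9))
  ps <- compute_phase_series(tr, make_beat_grid(120, 25), cfg)
  expect_equal(ps$phases_deg, -72)
  expect_equal(ps$beat_index, 21L) # beat at 10.0 s

  # exact hit and perfect synchrony
  expect_equal(compute_phase_series(
    movement_trial("s", "human", 120, 1, 1.0), grid, cfg)$phases_deg, 0)
  ps3 <- compute_phase_series(
    movement_trial("s", "human", 120, 1, c(0, 0.5, 1.0) + 1e-12), grid, cfg)
  expect_equal(ps3$phases_deg, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(ps3$intervals_s, c(0.5, 0.5))

  # half-period tie: default goes to the earlier beat (+180), switchable
  tie <- movement_trial("s", "human", 120, 1, 0.75)
  expect_equal(compute_phase_series(tie, grid, cfg)$beat_index, 2L)
  expect_equal(compute_phase_series(tie, grid, cfg)$phases_deg, 180)
  cfg_later <- analysis_config(nearest_beat_tie = "later")
  expect_equal(compute_phase_series(tie, grid, cfg_later)$beat_index, 3L)
  expect_equal(compute_phase_series(tie, grid, cfg_later)$phases_deg, 180)

  # events beyond the grid are excluded and counted
  far <- movement_trial("s", "human", 120, 1, c(0.1, 0.6, 30))
  expect_message(ps_far <- compute_phase_series(far, grid, cfg), "excluded")
  expect_length(ps_far$phases_deg, 2)
  expect_equal(ps_far$n_unmatched, 1L)
})

test_that("trial summaries report tempo and circular descriptives", {
  grid <- make_beat_grid(120, 25)
  s <- summarize_trial(offset_trial(0), grid)
  expect_equal(s$performed_tempo_bpm, 120)
  expect_equal(s$sd_tempo_bpm, 0)
  expect_equal(s$mean_phase_deg, 0)
  expect_equal(s$vector_length, 1)
  expect_equal(s$circ_sd_deg, 0)

  # constant -0.04 s offset on a 0.5 s period: -28.8 deg, perfectly coherent
  s2 <- summarize_trial(offset_trial(-0.04), grid)
  expect_equal(s2$mean_phase_deg, -28.8)
  expect_equal(s2$vector_length, 1)
  expect_equal(s2$n_events, 25L)

  expect_error(summarize_trial(
    movement_trial("s", "human", 120, 1, 0.1), grid), "at least 2")

  # reciprocal-of-mean-interval tempo method
  cfg_recip <- analysis_config(tempo_method = "reciprocal_of_mean_interval")
  tr <- movement_trial("s", "human", 120, 1, c(0, 0.4, 1.0))
  expect_equal(summarize_trial(tr, grid, cfg_recip)$performed_tempo_bpm,
               60 / 0.5)
  expect_equal(summarize_trial(tr, grid)$performed_tempo_bpm,
               mean(60 / c(0.4, 0.6)))
})

test_that("subject aggregates follow the linear/circular averaging rules", {
  grid <- make_beat_grid(120, 25)
  trials <- lapply(1:4, function(i) offset_trial(-0.04, trial_index = i))
  agg <- summarize_subject(trials, grid)
  one <- summarize_trial(trials[[1]], grid)
  expect_equal(agg$mean_tempo_bpm, one$performed_tempo_bpm)
  expect_equal(agg$mean_phase_deg, one$mean_phase_deg)
  expect_equal(agg$mean_vector_length, one$vector_length)
  expect_equal(agg$n_trials, 4L)

  # circular average of trial means: 10 and 30 deg -> 20 deg
  t10 <- offset_trial(10 / 360 * 0.5, trial_index = 1)
  t30 <- offset_trial(30 / 360 * 0.5, trial_index = 2)
  expect_equal(summarize_subject(list(t10, t30), grid)$mean_phase_deg, 20)

  # antipodal trial means surface the degenerate-direction error
  tp90 <- offset_trial(90 / 360 * 0.5, trial_index = 1)
  tm90 <- offset_trial(-90 / 360 * 0.5, trial_index = 2)
  expect_error(summarize_subject(list(tp90, tm90), grid), "undefined")

  mixed <- list(offset_trial(0), offset_trial(0, subject_id = "s2"))
  expect_error(summarize_subject(mixed, grid), "single subject")
})

test_that("phases and summaries are invariant to time origin and rotation", {
  cfg <- analysis_config()
  set.seed(7)
  tr <- generate_trial(subject_profile("s", "human", -20, 5), 120)
  grid <- make_beat_grid(120, 25)
  base <- compute_phase_series(tr, grid, cfg)
  for (shift in c(-2.5, 3.75)) {
    tr_s <- movement_trial(tr$subject_id, tr$group, tr$tempo_bpm, 1,
                           tr$event_times_s + shift)
    grid_s <- make_beat_grid(120, 25, t0 = shift)
    shifted <- compute_phase_series(tr_s, grid_s, cfg)
    expect_equal(shifted$phases_deg, base$phases_deg, tolerance = 1e-8)
    expect_equal(shifted$intervals_s, base$intervals_s, tolerance = 1e-10)
  }

  # flipping the sign convention negates phases and the mean, keeps R
  flipped <- compute_phase_series(tr, grid,
                                  analysis_config(phase_sign = "beat_minus_movement"))
  expect_equal(flipped$phases_deg, wrap_deg(-base$phases_deg))
  expect_equal(circular_mean(flipped$phases_deg),
               wrap_deg(-circular_mean(base$phases_deg)))
  expect_equal(vector_length(flipped$phases_deg),
               vector_length(base$phases_deg))

  # rotation: R invariant, mean rotates covariantly
  ph <- base$phases_deg
  for (rot in c(-130, 45, 200)) {
    expect_equal(vector_length(wrap_deg(ph + rot)), vector_length(ph),
                 tolerance = 1e-12)
    expect_equal(circular_mean(wrap_deg(ph + rot)),
                 wrap_deg(circular_mean(ph) + rot), tolerance = 1e-9)
  }
})

test_that("estimators recover Von Mises parameters at large N", {
  set.seed(31)
  n <- 1e4
  for (par in list(c(-35, 2), c(10, 6))) {
    x <- rvonmises(n, par[1], par[2])
    a_kappa <- besselI(par[2], 1, TRUE) / besselI(par[2], 0, TRUE)
    expect_lt(abs(circular_mean(x) - par[1]), 1.5) # degrees
    expect_lt(abs(vector_length(x) - a_kappa), 0.02)
  }
})
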