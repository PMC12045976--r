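#' Simulation configuration
#'
#' Parameters of the sliding-window Monte Carlo simulation of human beat
#' keeping. Defaults encode the study conditions the simulator models:
#' 10,000 trials per tempo, 24 chops per simulated trial, a 29-beat grid
#' (first onset at t = 0; the extra beats absorb skipped beats), window width
#' 4 chops, and a screening threshold of 0.4 on trial mean vector length.
#'
#' @param n_trials Simulated trials per tempo.
#' @param chops_per_trial Movements generated per simulated trial.
#' @param n_beats Beats in the simulation grid.
#' @param window_width Sliding-window width in chops.
#' @param screen_threshold Trials with vector length below this are removed
#'   before fitting.
#' @param max_rejections_per_chop Cap on rejection-sampling redraws for one
#'   chop before the simulation aborts (an inconsistent model fit).
#' @param window_rule How the generating window for chop `n` is chosen:
#'   `"trailing"` (default) uses the window whose last member is chop `n`,
#'   i.e. `clamp(n - width + 1, 1, n_windows)`, conditioning each draw on the
#'   most recent history; `"leading"` uses `clamp(n, 1, n_windows)`.
#' @param rng_seed Optional integer seed; when set, [simulate_cohort()] is
#'   fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_trials = 10000, chops_per_trial = 24, n_beats = 29,
                       window_width = 4, screen_threshold = 0.4,
                       max_rejections_per_chop = 10000,
                       window_rule = c("trailing", "leading"),
                       rng_seed = NULL) {
  stopifnot(n_trials >= 1, chops_per_trial >= 1, n_beats >= 1,
            window_width >= 1, screen_threshold >= 0, screen_threshold <= 1,
            max_rejections_per_chop >= 1)
  structure(
    list(n_trials = as.integer(n_trials),
         chops_per_trial = as.integer(chops_per_trial),
         n_beats = as.integer(n_beats),
         window_width = as.integer(window_width),
         screen_threshold = screen_threshold,
         max_rejections_per_chop = as.integer(max_rejections_per_chop),
         window_rule = match.arg(window_rule),
         rng_seed = rng_seed),
    class = "sim_config"
  )
}

#' Screen trials by vector length
#'
#' Removes trials whose mean vector length falls below the threshold before
#' the window models are fitted; only trials with reasonably coherent phase
#' behaviour inform the simulated cohort. The boundary is kept: only values
#' strictly below the threshold are removed.
#'
#' @param summaries Per-trial summary tibble ([summarize_trial()] rows).
#' @param threshold Minimum vector length retained (default 0.4).
#' @return List with `retained` (the surviving summary rows), `removed`
#'   (rows screened out) and `threshold`. An empty retained set is allowed
#'   but warned about loudly.
#' @export
screen_trials <- function(summaries, threshold = 0.4) {
  stopifnot(is.data.frame(summaries), "vector_length" %in% names(summaries))
  keep <- summaries$vector_length >= threshold
  if (!any(keep)) {
    warning("screening removed every trial (all vector lengths < ",
            threshold, ")", call. = FALSE)
  }
  list(retained = summaries[keep, , drop = FALSE],
       removed = summaries[!keep, , drop = FALSE],
       threshold = threshold)
}

#' Fit sliding-window interval and phase models
#'
#' Summarizes pooled movement behaviour at one tempo with overlapping
#' windows of `window_width` consecutive chops: window 1 covers chops 1-4,
#' window 2 chops 2-5, and so on, giving `L - width + 1` windows for maximal
#' trial length `L` (22 windows for 25-chop trials). Within each window the
#' pooled inter-chop intervals are fitted as a normal (mean, SD) and the
#' pooled phases as a Von Mises (circular mean, ML concentration). Chop 1
#' has no interval, so window 1 pools the intervals of chops 2 to
#' `width` only.
#'
#' @param series List of `phase_series` (one per screened trial at one
#'   tempo), as returned by [compute_phase_series()].
#' @param cfg A [sim_config()].
#' @return Tibble of window models: `window_index, interval_mu_s,
#'   interval_sigma_s, phase_mu_deg, phase_kappa, n_phase_obs,
#'   n_interval_obs`.
#' @details Concentrations are capped at `1e5` (degenerate, effectively
#'   point-mass windows). A window with fewer than 2 phase or 2 interval
#'   observations is a fitting error naming the window.
#' @export
fit_window_models <- function(series, cfg = sim_config()) {
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, TRUE, "phase_series")))
  width <- cfg$window_width
  len <- max(vapply(series, function(s) length(s$phases_deg), 0L))
  n_windows <- len - width + 1L
  if (n_windows < 1L) {
    stop("trials shorter than the window width", call. = FALSE)
  }
  rows <- lapply(seq_len(n_windows), function(k) {
    chops <- k:(k + width - 1L)
    phases <- unlist(lapply(series, function(s) {
      idx <- chops[chops <= length(s$phases_deg)]
      s$phases_deg[idx]
    }))
    intervals <- unlist(lapply(series, function(s) {
      # interval of chop n is s$intervals_s[n - 1]; chop 1 has none
      idx <- chops[chops >= 2L] - 1L
      idx <- idx[idx <= length(s$intervals_s)]
      s$intervals_s[idx]
    }))
    if (length(phases) < 2L || length(intervals) < 2L) {
      stop(sprintf("window %d: too few observations to fit (%d phases, %d intervals)",
                   k, length(phases), length(intervals)), call. = FALSE)
    }
    r <- vector_length(phases)
    tibble::tibble(
      window_index = k,
      interval_mu_s = mean(intervals),
      interval_sigma_s = stats::sd(intervals),
      phase_mu_deg = circular_mean(phases),
      phase_kappa = fit_kappa(min(r, 1 - 1e-12)),
      n_phase_obs = length(phases),
      n_interval_obs = length(intervals)
    )
  })
  dplyr::bind_rows(rows)
}

window_for_chop <- function(n, width, n_windows, rule) {
  idx <- if (rule == "trailing") n - width + 1L else n
  min(max(idx, 1L), n_windows)
}

#' Simulate one beat-keeping trial
#'
#' Generates one synthetic human trial from fitted window models by the
#' sequential interval/phase scheme: the first chop's phase is drawn from
#' window 1's Von Mises and converted to an onset time relative to the first
#' beat of a fresh `n_beats` grid (first onset at t = 0). Each subsequent
#' chop's interval is drawn from the normal of that chop's window, the
#' resulting onset's phase is computed against the nearest beat, and the
#' phase is validated against the window's Von Mises by rejection sampling
#' (acceptance probability = density normalized by its mode); on rejection
#' the interval is redrawn. Negative proposed intervals are rejected
#' outright.
#'
#' @param models Window-model tibble from [fit_window_models()].
#' @param tempo_bpm Stimulus tempo of the simulated trial.
#' @param cfg A [sim_config()].
#' @param return_events If `TRUE`, also return the chop onset times and
#'   phases.
#' @return One-row tibble with `mean_interval_s, mean_tempo_bpm,
#'   mean_phase_deg, vector_length` (plus list-columns `onsets_s` and
#'   `phases_deg` when `return_events = TRUE`). Draws use R's global RNG.
#' @export
simulate_trial <- function(models, tempo_bpm, cfg = sim_config(),
                           return_events = FALSE) {
  stopifnot(is.data.frame(models), nrow(models) >= 1L)
  period <- 60 / tempo_bpm
  n_windows <- nrow(models)
  n_chops <- cfg$chops_per_trial
  last_beat <- cfg$n_beats - 1L # beats are k * period, k = 0..n_beats-1

  onsets <- numeric(n_chops)
  phases <- numeric(n_chops)
  phases[1] <- rvonmises(1, models$phase_mu_deg[1], models$phase_kappa[1])
  onsets[1] <- 0 + phases[1] / 360 * period

  for (n in 2:n_chops) {
    w <- window_for_chop(n, cfg$window_width, n_windows, cfg$window_rule)
    mu_i <- models$interval_mu_s[w]
    sd_i <- models$interval_sigma_s[w]
    mu_p <- models$phase_mu_deg[w]
    kap <- models$phase_kappa[w]
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > cfg$max_rejections_per_chop) {
        stop(sprintf(
          "chop %d (window %d): exceeded %d rejection-sampling attempts; window model is inconsistent",
          n, w, cfg$max_rejections_per_chop), call. = FALSE)
      }
      interval <- stats::rnorm(1, mu_i, sd_i)
      if (interval <= 0) next
      onset <- onsets[n - 1] + interval
      beat <- min(max(round(onset / period), 0), last_beat)
      phase <- wrap_deg(360 * (onset - beat * period) / period)
      if (kap <= 0 || stats::runif(1) < vm_accept_prob(phase, mu_p, kap)) {
        onsets[n] <- onset
        phases[n] <- phase
        break
      }
    }
  }
  intervals <- diff(onsets)
  out <- tibble::tibble(
    mean_interval_s = mean(intervals),
    mean_tempo_bpm = mean(60 / intervals),
    mean_phase_deg = circular_mean(phases),
    vector_length = vector_length(phases)
  )
  if (return_events) {
    out$onsets_s <- list(onsets)
    out$phases_deg <- list(phases)
  }
  out
}

#' Simulate a cohort of beat-keeping trials
#'
#' Draws `cfg$n_trials` independent trials from [simulate_trial()] and
#' aggregates them. With `cfg$rng_seed` set, the whole cohort is a pure
#' function of (models, seed).
#'
#' @inheritParams simulate_trial
#' @return An object of class `sim_cohort`: list with `tempo_bpm`, `trials`
#'   (per-trial tibble), `aggregate` (mean/SD of trial mean tempos in bpm,
#'   mean of trial mean intervals in seconds, circular mean of trial mean
#'   phases, mean vector length) and `rng_seed`.
#' @export
simulate_cohort <- function(models, tempo_bpm, cfg = sim_config()) {
  run <- function() {
    dplyr::bind_rows(lapply(seq_len(cfg$n_trials), function(i) {
      simulate_trial(models, tempo_bpm, cfg)
    }))
  }
  trials <- if (is.null(cfg$rng_seed)) run() else
    withr::with_seed(cfg$rng_seed, run())
  aggregate <- list(
    mean_tempo_bpm = mean(trials$mean_tempo_bpm),
    sd_tempo_bpm = stats::sd(trials$mean_tempo_bpm),
    mean_interval_s = mean(trials$mean_interval_s),
    mean_phase_deg = circular_mean(trials$mean_phase_deg),
    mean_vector_length = mean(trials$vector_length)
  )
  structure(
    list(tempo_bpm = tempo_bpm, trials = trials, aggregate = aggregate,
         rng_seed = cfg$rng_seed),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<sim_cohort> %g bpm, %d trials: tempo %.2f +- %.2f bpm, phase %+.2f deg, R = %.3f\n",
    x$tempo_bpm, nrow(x$trials), a$mean_tempo_bpm, a$sd_tempo_bpm,
    a$mean_phase_deg, a$mean_vector_length))
  invisible(x)
}

#' z-test of an observed value against a simulated cohort
#'
#' Treats the cohort's per-trial statistics as approximately normal (the
#' cohort is large) and locates the observed value within them:
#' `z = (observed - mean) / SD`, two-tailed p. Circular observables are
#' compared on the linear degree scale after wrapping to (-180, 180], which
#' is adequate for cohorts concentrated well away from the +-180 cut.
#'
#' @param observed Observed scalar (e.g. one real trial's mean phase).
#' @param cohort_values Numeric vector of the cohort's per-trial values,
#'   length >= 100.
#' @param circular Wrap both sides to (-180, 180] before comparing.
#' @return A `circ_test` with the z statistic and two-tailed p-value.
#' @export
z_test_vs_cohort <- function(observed, cohort_values, circular = FALSE) {
  stopifnot(is.numeric(observed), length(observed) == 1L)
  if (length(cohort_values) < 100L) {
    stop("cohort too small for a z-test (need >= 100 values)", call. = FALSE)
  }
  if (circular) {
    observed <- wrap_deg(observed)
    cohort_values <- wrap_deg(cohort_values)
  }
  s <- stats::sd(cohort_values)
  if (s <= 0) stop("cohort SD is zero: z undefined", call. = FALSE)
  z <- (observed - mean(cohort_values)) / s
  new_circ_test("z_test", z, 2 * stats::pnorm(-abs(z)),
                n = length(cohort_values),
                extra = list(cohort_mean = mean(cohort_values),
                             cohort_sd = s))
}

#' Fraction of simulated trials farther from synchrony than an observation
#'
#' Percentile companion to the z-test: the fraction of cohort trials whose
#' absolute mean phase exceeds the observed absolute mean phase (larger is
#' better for the observed subject), plus the signed variant — the fraction
#' of cohort trials with a mean phase more negative than the observation
#' (i.e. the observation is "more positive than" that fraction of the
#' cohort).
#'
#' @param observed_phase_deg Observed mean phase, degrees.
#' @param cohort_phases_deg Cohort per-trial mean phases, degrees.
#' @return List with `abs_exceedance`, `signed_more_negative` (both
#'   fractions in \[0, 1\]) and the corresponding counts and `n`.
#' @export
exceedance_fraction <- function(observed_phase_deg, cohort_phases_deg) {
  stopifnot(length(cohort_phases_deg) >= 1L)
  obs <- wrap_deg(observed_phase_deg)
  coh <- wrap_deg(cohort_phases_deg)
  n_abs <- sum(abs(coh) > abs(obs))
  n_neg <- sum(coh < obs)
  list(
    abs_exceedance = n_abs / length(coh),
    signed_more_negative = n_neg / length(coh),
    n_abs_exceeding = n_abs,
    n_more_negative = n_neg,
    n = length(coh)
  )
}
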