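#' Subject profile for the synthetic study generator
#'
#' Ground-truth parameters of one synthetic subject's beat-keeping
#' behaviour.
#'
#' @param subject_id Unique identifier.
#' @param group One of `"sea_lion"`, `"human"`, `"simulated"`, `"synthetic"`.
#' @param phase_mu_deg Target mean asynchrony in degrees (negative = moves
#'   before the beat).
#' @param phase_kappa Von Mises concentration of the per-beat phase noise
#'   (>= 0); governs both vector length and, in the beat-anchored generator,
#'   the emergent interval variability.
#' @param tempo_bias_bpm Systematic performed-tempo error in bpm.
#' @param interval_cv Coefficient of variation of intervals; used by the
#'   interval-walk generation mode only (>= 0).
#' @param drift_deg_per_chop Linear within-trial phase drift, degrees per
#'   chop, centred on the trial midpoint so the trial mean stays at
#'   `phase_mu_deg`.
#' @param skip_prob Probability that a beat receives no movement, in
#'   \[0, 0.2\].
#' @param phase_ar1 Lag-1 autocorrelation of the phase noise, in \[0, 1).
#'   At 0 (the default) per-beat phases are independent Von Mises draws; for
#'   `phase_ar1 > 0` the noise is a wrapped stationary AR(1) Gaussian whose
#'   marginal resultant length is matched to the Von Mises `A(kappa)`, which
#'   emulates the slowly wandering asynchronies of real movement (and keeps
#'   inter-movement intervals smooth) without changing the marginal
#'   concentration.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group, phase_mu_deg, phase_kappa,
                            tempo_bias_bpm = 0, interval_cv = 0.05,
                            drift_deg_per_chop = 0, skip_prob = 0,
                            phase_ar1 = 0) {
  group <- match.arg(group, trial_groups)
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            phase_kappa >= 0, interval_cv >= 0,
            skip_prob >= 0, skip_prob <= 0.2,
            phase_ar1 >= 0, phase_ar1 < 1)
  structure(
    list(subject_id = subject_id, group = group,
         phase_mu_deg = phase_mu_deg, phase_kappa = phase_kappa,
         tempo_bias_bpm = tempo_bias_bpm, interval_cv = interval_cv,
         drift_deg_per_chop = drift_deg_per_chop, skip_prob = skip_prob,
         phase_ar1 = phase_ar1),
    class = "subject_profile"
  )
}

# Centered phase noise in degrees: independent Von Mises draws when rho = 0,
# and a stationary AR(1) Gaussian otherwise. The AR path is returned
# *unwrapped* (it feeds event-time construction, where wrapping would
# teleport events backwards across the +-180 cut); once the analysis wraps
# the measured phases, the marginal is a wrapped normal whose resultant
# length equals the Von Mises A(kappa) by construction of sigma.
phase_noise <- function(n, kappa, rho) {
  if (kappa < 1e-8) return(wrap_deg(stats::runif(n, -180, 180)))
  if (rho <= 0) return(rvonmises(n, 0, kappa))
  sigma <- sqrt(-2 * log(bessel_ratio(kappa))) # radians
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  innov <- stats::rnorm(n - 1, 0, sigma * sqrt(1 - rho^2))
  for (i in seq_len(n - 1)) x[i + 1] <- rho * x[i] + innov[i]
  rad2deg(x)
}

#' Study design for the synthetic generator
#'
#' Defaults mirror the comparative study layout the analysis targets: three
#' test tempos (112, 120, 128 bpm) presented in four successive blocks (4
#' trials per tempo, 12 test trials per subject), 25 beats per trial, ten
#' human subjects plus one expert subject.
#'
#' @param tempos_bpm Stimulus tempos.
#' @param trials_per_tempo Exposures per subject per tempo.
#' @param beats_per_trial Beats per stimulus presentation.
#' @param n_humans Number of human-profile subjects.
#' @param include_expert Include the expert (sea-lion-profile) subject.
#' @param rng_seed Optional integer seed for [generate_study()].
#' @return An object of class `study_design`.
#' @export
study_design <- function(tempos_bpm = c(112, 120, 128), trials_per_tempo = 4,
                         beats_per_trial = 25, n_humans = 10,
                         include_expert = TRUE, rng_seed = NULL) {
  stopifnot(length(tempos_bpm) >= 1, all(tempos_bpm > 0),
            trials_per_tempo >= 1, beats_per_trial >= 2, n_humans >= 0)
  structure(
    list(tempos_bpm = tempos_bpm,
         trials_per_tempo = as.integer(trials_per_tempo),
         beats_per_trial = as.integer(beats_per_trial),
         n_humans = as.integer(n_humans),
         include_expert = isTRUE(include_expert),
         rng_seed = rng_seed),
    class = "study_design"
  )
}

#' Default subject profiles
#'
#' One expert subject plus ten heterogeneous human subjects, calibrated so
#' the synthetic study reproduces the qualitative structure of real
#' gross-movement beat-keeping data: humans cluster around a mean asynchrony
#' near -16 degrees with wide between-subject spread in concentration
#' (trial vector lengths from near 0 to near 1) and tempo accuracy, while
#' the expert is slightly fast, clearly negative in phase, and more
#' concentrated than almost all humans (so she beats most of them on
#' interval SD and vector length, but not everyone on everything).
#'
#' @param n_humans Number of human profiles to return (up to 10).
#' @param include_expert Prepend the expert profile.
#' @return List of [subject_profile()] objects.
#' @export
default_profiles <- function(n_humans = 10, include_expert = TRUE) {
  stopifnot(n_humans >= 0, n_humans <= 10)
  humans <- list(
    subject_profile("h01", "human", -5,  5.0,  0.5, phase_ar1 = 0.4),
    subject_profile("h02", "human", -25, 3.5, -1.0,
                    drift_deg_per_chop = -0.5, phase_ar1 = 0.4),
    subject_profile("h03", "human", -45, 2.0,  2.0,
                    drift_deg_per_chop = 0.5, phase_ar1 = 0.75),
    subject_profile("h04", "human", 10,  5.0, -0.5, phase_ar1 = 0.4),
    subject_profile("h05", "human", -60, 1.0,  3.0,
                    drift_deg_per_chop = -1, phase_ar1 = 0.92),
    subject_profile("h06", "human", -10, 5.5,  0.2, phase_ar1 = 0.4),
    subject_profile("h07", "human", -30, 0.6, -2.0,
                    drift_deg_per_chop = 1, phase_ar1 = 0.92),
    subject_profile("h08", "human", 25,  2.5,  1.0, phase_ar1 = 0.75),
    subject_profile("h09", "human", -20, 4.5, -0.3,
                    drift_deg_per_chop = -0.3, phase_ar1 = 0.4),
    subject_profile("h10", "human", 0,   0.3,  4.0, phase_ar1 = 0.92)
  )[seq_len(n_humans)]
  if (include_expert) {
    expert <- subject_profile("expert", "sea_lion", -20, 8.0, 0.5,
                              interval_cv = 0.03,
                              drift_deg_per_chop = -0.4, phase_ar1 = 0.7)
    c(list(expert), humans)
  } else {
    humans
  }
}

#' Generate one synthetic trial
#'
#' Beat-anchored mode (default): each un-skipped beat `k` receives a phase
#' drawn from a Von Mises centred at
#' `phase_mu + d * (k - midpoint)` with concentration `phase_kappa`, and the
#' event time is the beat onset plus `phase/360 * period`. The slope `d`
#' combines the profile's explicit drift with the slope implied by the tempo
#' bias, `-360 * b / (T + b)` degrees per beat, which makes the expected
#' performed tempo exactly `T + b`; centring on the trial midpoint keeps the
#' expected trial circular mean at `phase_mu_deg`. Ground-truth phase
#' parameters are therefore exact by construction.
#'
#' Interval-walk mode: the first event is a phase draw around beat one, and
#' subsequent events accumulate intervals drawn from
#' `Normal(60/(T + b), interval_cv * 60/(T + b))` (negative proposals
#' redrawn), a rougher emulation in which phase is free to wander.
#'
#' @param profile A [subject_profile()].
#' @param tempo_bpm Stimulus tempo.
#' @param n_beats Beats in the trial.
#' @param trial_index Trial index recorded on the result.
#' @param mode `"beat_anchored"` (default) or `"interval_walk"`.
#' @return A [movement_trial()]. Draws use R's global RNG stream.
#' @details Generation fails (rather than silently reordering) if the
#'   parameter combination yields non-monotone event times.
#' @export
generate_trial <- function(profile, tempo_bpm, n_beats = 25, trial_index = 1,
                           mode = c("beat_anchored", "interval_walk")) {
  stopifnot(inherits(profile, "subject_profile"), tempo_bpm > 0, n_beats >= 2)
  mode <- match.arg(mode)
  period <- 60 / tempo_bpm
  bias <- profile$tempo_bias_bpm
  d_bias <- -360 * bias / (tempo_bpm + bias)
  d <- profile$drift_deg_per_chop + d_bias

  if (mode == "beat_anchored") {
    k <- 0:(n_beats - 1)
    keep <- stats::runif(n_beats) >= profile$skip_prob
    if (sum(keep) < 2L) {
      stop("skip_prob left fewer than 2 events in the trial", call. = FALSE)
    }
    mid <- (n_beats - 1) / 2
    mu_k <- profile$phase_mu_deg + d * (k - mid)
    noise <- phase_noise(n_beats, profile$phase_kappa, profile$phase_ar1)
    # event times use the *unwrapped* phase: a subject drifting past half a
    # cycle physically slides toward the neighbouring beat rather than
    # teleporting backwards, which keeps intervals smooth; the analysis
    # pipeline later measures phases wrapped against the nearest beat
    times <- (k * period + (mu_k + noise) / 360 * period)[keep]
  } else {
    target <- 60 / (tempo_bpm + bias)
    phase1 <- wrap_deg(profile$phase_mu_deg +
                         rvonmises(1, 0, profile$phase_kappa))
    n_events <- n_beats
    intervals <- numeric(n_events - 1)
    for (i in seq_len(n_events - 1)) {
      repeat {
        iv <- stats::rnorm(1, target, profile$interval_cv * target)
        if (iv > 0) break
      }
      intervals[i] <- iv
    }
    times <- cumsum(c(phase1 / 360 * period, intervals))
  }
  if (any(diff(times) <= 0)) {
    stop(sprintf(
      "profile %s produced non-monotone event times (drift/skip too extreme)",
      profile$subject_id), call. = FALSE)
  }
  movement_trial(profile$subject_id, profile$group, tempo_bpm,
                 trial_index, times)
}

#' Generate a complete synthetic study
#'
#' Produces the full long-format trials table for a study design and set of
#' subject profiles (every subject, every tempo, every trial), together with
#' the ground-truth parameter table used to generate it. Deterministic under
#' the design's (or the supplied) seed.
#'
#' @param design A [study_design()].
#' @param profiles List of [subject_profile()] objects, unique ids, count
#'   equal to `n_humans + include_expert`.
#' @param rng_seed Seed; overrides `design$rng_seed` when given.
#' @param mode Generation mode passed to [generate_trial()].
#' @return List with `trials` (long event tibble in the [read_trials()]
#'   schema), `truth` (tibble of profile parameters), `trial_list` (the
#'   `movement_trial` objects) and `design`.
#' @export
generate_study <- function(design = study_design(),
                           profiles = default_profiles(),
                           rng_seed = NULL,
                           mode = c("beat_anchored", "interval_walk")) {
  mode <- match.arg(mode)
  ids <- vapply(profiles, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id in profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  expected <- design$n_humans + as.integer(design$include_expert)
  if (length(profiles) != expected) {
    stop(sprintf("design expects %d profiles, got %d", expected,
                 length(profiles)), call. = FALSE)
  }
  seed <- if (!is.null(rng_seed)) rng_seed else design$rng_seed
  build <- function() {
    trial_list <- list()
    for (prof in profiles) {
      for (tempo in design$tempos_bpm) {
        for (trial in seq_len(design$trials_per_tempo)) {
          trial_list[[length(trial_list) + 1L]] <-
            generate_trial(prof, tempo, design$beats_per_trial, trial, mode)
        }
      }
    }
    trial_list
  }
  trial_list <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  truth <- dplyr::bind_rows(lapply(profiles, function(p) {
    tibble::tibble(
      subject_id = p$subject_id, group = p$group,
      phase_mu_deg = p$phase_mu_deg, phase_kappa = p$phase_kappa,
      tempo_bias_bpm = p$tempo_bias_bpm, interval_cv = p$interval_cv,
      drift_deg_per_chop = p$drift_deg_per_chop, skip_prob = p$skip_prob,
      phase_ar1 = p$phase_ar1
    )
  }))
  list(trials = trials_to_table(trial_list), truth = truth,
       trial_list = trial_list, design = design)
}
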