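test_that("screening keeps the boundary and is monotone in the threshold", {
  sm <- tibble::tibble(trial = 1:3, vector_length = c(0.39, 0.40, 0.95))
  sc <- screen_trials(sm, 0.4)
  expect_equal(sc$retained$trial, c(2, 3)) # exactly 0.4 is kept
  expect_equal(sc$removed$trial, 1)

  all_good <- tibble::tibble(trial = 1:4, vector_length = c(0.4, 0.6, 0.8, 1))
  expect_identical(screen_trials(all_good, 0.4)$retained, all_good)
  expect_warning(sc0 <- screen_trials(sm, 0.99), "removed every trial")
  expect_equal(nrow(sc0$retained), 0)

  counts <- vapply(seq(0, 1, by = 0.05), function(th) {
    nrow(suppressWarnings(screen_trials(sm, th))$retained)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("window fitting pools the documented chops and intervals", {
  # one 25-chop trial, width 4: 22 windows; window 1 = chops 1-4 with the 3
  # intervals ending at chops 2-4, later windows carry 4 intervals
  ph <- seq(-24, 24, by = 2) # 25 distinct phases
  iv <- seq(0.41, 0.64, by = 0.01) # 24 distinct intervals
  s <- manual_phase_series(ph, iv)
  models <- fit_window_models(list(s), sim_config())
  expect_equal(nrow(models), 22)
  expect_equal(models$n_phase_obs, rep(4L, 22))
  expect_equal(models$n_interval_obs, c(3L, rep(4L, 21)))
  expect_equal(models$interval_mu_s[1], mean(iv[1:3]))
  expect_equal(models$interval_mu_s[2], mean(iv[1:4]))
  expect_equal(models$phase_mu_deg[1], circular_mean(ph[1:4]))
  expect_equal(models$phase_mu_deg[22], circular_mean(ph[22:25]))

  # degenerate inputs: zero spread, capped concentration
  sd0 <- manual_phase_series(rep(0, 25), rep(0.5, 24))
  m0 <- fit_window_models(list(sd0), sim_config())
  expect_equal(m0$interval_mu_s, rep(0.5, 22))
  expect_equal(m0$interval_sigma_s, rep(0, 22))
  expect_equal(m0$phase_mu_deg, rep(0, 22))
  expect_true(all(m0$phase_kappa >= 1e4))

  expect_error(fit_window_models(list(manual_phase_series(c(1, 2), 0.5)),
                                 sim_config()),
               "window")
})

test_that("window fits recover known generating parameters", {
  # generate-then-refit: trials built from per-window truths
  set.seed(55)
  truth_mu <- seq(-30, 12, length.out = 22)
  truth_iv <- seq(0.48, 0.52, length.out = 22)
  kappa <- 12
  mk_trial <- function() {
    win <- pmin(pmax(1:25 - 3, 1), 22) # trailing window per chop
    ph <- vapply(win, function(w) rvonmises(1, truth_mu[w], kappa), 0)
    iv <- vapply(win[-1], function(w) rnorm(1, truth_iv[w], 0.01), 0)
    manual_phase_series(ph, iv)
  }
  series <- replicate(120, mk_trial(), simplify = FALSE)
  models <- fit_window_models(series, sim_config())
  se <- models$interval_sigma_s / sqrt(models$n_interval_obs)
  z <- abs(models$interval_mu_s -
             vapply(1:22, function(k) {
               chops <- k:(k + 3)
               win <- pmin(pmax(chops - 3, 1), 22)
               mean(truth_iv[win[chops >= 2]])
             }, 0)) / se
  expect_lt(mean(z > 2), 0.2) # ~95% coverage, allow sampling slack
  expect_true(all(z < 4))
  mu_expected <- vapply(1:22, function(k) {
    win <- pmin(pmax(k:(k + 3) - 3, 1), 22)
    circular_mean(truth_mu[win]) # pooled target across the window's chops
  }, 0)
  expect_true(all(abs(wrap_deg(models$phase_mu_deg - mu_expected)) < 5))
})

test_that("simulated trials honour degenerate and uniform limits", {
  m <- degenerate_models(22, 0.5, 0, 1e5)
  set.seed(4)
  tr <- simulate_trial(m, 120, return_events = TRUE)
  expect_equal(tr$mean_tempo_bpm, 120) # intervals exactly the beat period
  expect_equal(tr$mean_interval_s, 0.5)
  expect_lt(abs(tr$mean_phase_deg), 1)
  expect_gt(tr$vector_length, 0.999)
  expect_length(tr$onsets_s[[1]], 24)

  # kappa = 0 windows accept every proposal: acceptance probability is 1
  expect_equal(beatsync:::vm_accept_prob(c(-180, -45, 0, 90), 10, 0),
               rep(1, 4))
  # and acceptance decreases with angular distance for kappa > 0
  dist <- seq(0, 180, by = 15)
  acc <- beatsync:::vm_accept_prob(10 + dist, 10, 2.5)
  expect_true(all(diff(acc) < 0))
  expect_equal(acc[1], 1)

  # inconsistent models (point-mass interval against a distant point-mass
  # phase) exhaust the rejection budget and name the chop
  bad <- degenerate_models(22, 0.5, 0, 1e5)
  bad$phase_mu_deg[5:22] <- 170
  bad$interval_sigma_s <- 1e-9
  cfg_small <- sim_config(max_rejections_per_chop = 50)
  set.seed(9)
  expect_error(simulate_trial(bad, 120, cfg_small), "rejection-sampling")
})

test_that("cohorts are reproducible and exact in the degenerate limit", {
  m <- degenerate_models(22, 60 / 112, 0, 1e5)
  cfg <- sim_config(n_trials = 120, rng_seed = 77)
  c1 <- simulate_cohort(m, 112, cfg)
  c2 <- simulate_cohort(m, 112, cfg)
  expect_identical(c1$trials, c2$trials)
  expect_equal(c1$aggregate$mean_tempo_bpm, 112)
  expect_equal(c1$aggregate$sd_tempo_bpm, 0)
  expect_equal(nrow(c1$trials), 120)

  cfg2 <- sim_config(n_trials = 120, rng_seed = 78)
  expect_false(identical(simulate_cohort(m, 112, cfg2)$trials, c1$trials))
})

test_that("uniform-phase windows yield uniform simulated phases", {
  # wide interval noise (half a period) decorrelates successive phases, so
  # the pooled sample is effectively independent for the GOF test
  m <- degenerate_models(22, 0.5, 0, 0)
  m$interval_sigma_s <- 0.25
  cfg <- sim_config(n_trials = 400, rng_seed = 5)
  ph <- withr::with_seed(41, unlist(lapply(1:400, function(i) {
    simulate_trial(m, 120, cfg, return_events = TRUE)$phases_deg[[1]][-1]
  })))
  # goodness of fit against uniform on (-180, 180], not rejected at 1% level
  bins <- cut(ph, breaks = seq(-180, 180, by = 20), include.lowest = TRUE)
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)
})

test_that("simulated mean phase recovers the phases the models encode", {
  set.seed(23)
  prof <- lapply(1:6, function(i) {
    subject_profile(sprintf("p%02d", i), "human", -15, 4,
                    tempo_bias_bpm = 0)
  })
  trials <- unlist(lapply(prof, function(p) {
    lapply(1:4, function(j) generate_trial(p, 120, 25, j))
  }), recursive = FALSE)
  series <- study_phase_series(trials)
  models <- fit_window_models(series, sim_config())
  coh <- simulate_cohort(models, 120, sim_config(n_trials = 2000,
                                                 rng_seed = 61))
  expect_lt(abs(coh$aggregate$mean_phase_deg - -15), 3)
  # intervals are unbiased in seconds (mean instantaneous bpm carries the
  # usual Jensen inflation, so the check is on the interval scale)
  expect_lt(abs(60 / coh$aggregate$mean_interval_s - 120), 1)
})

test_that("z-test and exceedance locate an observation within a cohort", {
  vals <- withr::with_seed(19, rnorm(1000, -15, 4))
  at_mean <- z_test_vs_cohort(mean(vals), vals)
  expect_equal(at_mean$statistic, 0, tolerance = 1e-12)
  expect_equal(at_mean$p_value, 1)
  at_196 <- z_test_vs_cohort(mean(vals) + 1.96 * sd(vals), vals)
  expect_equal(at_196$p_value, 0.05, tolerance = 0.001)
  expect_error(z_test_vs_cohort(0, rnorm(50)), ">= 100")
  expect_error(z_test_vs_cohort(0, rep(1, 200)), "SD is zero")

  ex <- exceedance_fraction(-6, c(-10, -5, 20))
  expect_equal(ex$abs_exceedance, 2 / 3)
  expect_equal(ex$signed_more_negative, 1 / 3)
  expect_equal(exceedance_fraction(0, c(-10, -5, 20))$abs_exceedance, 1)
  expect_equal(exceedance_fraction(200, c(-10, -5, 20))$abs_exceedance, 0)
  # brute-force counting oracle on a random cohort
  coh <- withr::with_seed(29, runif(500, -180, 180))
  obs <- -23.4
  brute <- sum(vapply(coh, function(x) abs(x) > abs(obs), TRUE))
  expect_equal(exceedance_fraction(obs, coh)$n_abs_exceeding, brute)
})

test_that("cohorts show the tempo-error/vector-length U-shape", {
  set.seed(83)
  prof <- lapply(1:6, function(i) {
    subject_profile(sprintf("q%02d", i), "human", -15, 3)
  })
  trials <- unlist(lapply(prof, function(p) {
    lapply(1:4, function(j) generate_trial(p, 120, 25, j))
  }), recursive = FALSE)
  models <- fit_window_models(study_phase_series(trials), sim_config())
  coh <- simulate_cohort(models, 120, sim_config(n_trials = 1500,
                                                 rng_seed = 31))
  ct <- suppressWarnings(stats::cor.test(
    abs(coh$trials$mean_tempo_bpm - 120), coh$trials$vector_length,
    method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
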