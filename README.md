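# beatsync

Circular statistics and Monte Carlo modelling of sensorimotor
synchronization (beat keeping): the analysis a comparative-rhythm study
needs when a subject — human or otherwise — times discrete movements to an
isochronous metronome and you want to say, quantitatively, how well.

It is written for researchers analysing movement-event time series (the
times of head-bob or arm-chop nadirs per trial, plus the stimulus tempo)
and provides, as a tested reusable package:

* **Phase metrics** — each movement matched to its nearest beat, timing
  error expressed as a phase angle
  `θᵢ = 360 (t_event − t_beat) / dt` in `(−180°, 180°]` (negative = the
  movement precedes the beat, i.e. negative mean asynchrony), with circular
  descriptives: mean direction `θ̄`, mean resultant vector length
  `R̄ = |N⁻¹ Σ exp(iθₙ)|`, circular SD `√(−2 ln R̄)`, performed tempo in bpm.
* **The circular test battery** — Rayleigh uniformity test (`z = N R̄²`,
  higher-order series p-value): *entrainment*; V-test against 0°
  (`u = R̄ cos(θ̄ − μ₀) √(2N)`): *synchronization*; Watson–Williams F-test
  of equal mean directions with the `1 + 3/(8κ̂)` correction and explicit
  `df = (k−1, N−k)`; ML Von Mises concentration by Bessel-ratio inversion.
* **A sliding-window Monte Carlo simulator of human beat keeping** —
  screen trials at vector length 0.4, pool survivors into overlapping
  4-chop windows (22 windows for 25-chop trials), fit a normal to each
  window's intervals and a Von Mises to its phases, then generate 10,000
  trials per tempo on a 29-beat grid by sequential interval draws with
  rejection-sampled phases; locate an observed subject in the cohort by
  z-test and exceedance fraction.
* **Comparison procedures** — rank-ordering a focal subject against
  comparators on tempo error, interval SD, |mean phase| and vector length
  (ties are not wins); first-vs-last-trial learning checks; first-12 vs
  last-12 chop within-trial drift comparisons.
* **A synthetic study generator** — ten heterogeneous humans plus one
  expert subject, 4 trials × 3 tempos (112/120/128 bpm) × 25 beats, with
  exact ground-truth parameters (mean asynchrony, concentration, tempo
  bias, drift, phase autocorrelation) for end-to-end parameter-recovery
  testing without any data download.

The methods vignette (`vignettes/beatkeeping-methods.Rmd`) documents the
model, conventions and numerical choices in detail.

## Worked example

```r
library(beatsync)

st   <- generate_study(study_design(rng_seed = 42))
tr   <- st$trial_list[[1]]            # expert subject, 112 bpm, trial 1
grid <- make_beat_grid(112, 25)       # 25 beats, first onset at t = 0

summarize_trial(tr, grid)[6:12]
#>   mean_interval_s sd_interval_s performed_tempo_bpm sd_tempo_bpm mean_phase_deg
#> 1           0.532         0.022             112.968        4.673         -0.525
#>   vector_length circ_sd_deg
#> 1         0.904      25.793

ph <- compute_phase_series(tr, grid)$phases_deg
rayleigh_test(ph)
#> <circ_test> rayleigh: statistic = 20.41, p = 3.59e-09, n = 25
#>   mean angle = -0.52 deg
v_test(ph, 0)
#> <circ_test> v_test: statistic = 6.389, p = 8.326e-11, n = 25
#>   mean angle = -0.52 deg
```

Reading: across this 25-beat trial the expert performed at ≈ 113 bpm
against a 112 bpm stimulus, with movements centred half a degree before the
beat and a vector length of 0.90 (tightly concentrated). The Rayleigh test
rejects uniformity (entrained) and the V-test rejects uniformity in favour
of clustering at 0° (synchronized, not merely entrained).

## The analysis workflow

The study-level analyses live as numbered drivers under `analysis/`, each a
thin script over the package functions that narrates what it finds and
writes its tables under `results/`:

1. `01_generate_synthetic_study.R` — the synthetic study (long-format event
   table + ground truth).
2. `02_summarize_trials.R` — per-trial and per-subject circular summaries.
3. `03_entrainment_tests.R` — Rayleigh/V per trial; Watson–Williams across
   tempos; first-vs-last and within-trial-half comparisons.
4. `04_simulate_cohorts.R` — screening, window fits, 10,000 simulated
   trials per tempo.
5. `05_compare_expert.R` — rank tables and expert-vs-cohort z-tests /
   exceedance fractions.

Run them in order from the repository root
(`Rscript analysis/01_generate_synthetic_study.R`, …). Real data enter the
same pipeline through `read_trials()`, a UTF-8 CSV with columns
`subject_id, group, tempo_bpm, trial_index, event_index, time_s` (times in
seconds, first beat onset of each trial at 0) — the documented export
format for trial-by-trial spreadsheet data.

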