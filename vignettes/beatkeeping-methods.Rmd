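---
title: "Circular statistics and Monte Carlo modelling of beat keeping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular statistics and Monte Carlo modelling of beat keeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

A beat-keeping trial presents a subject with an isochronous metronome —
`n` beats at tempo `T` bpm, so one beat every `dt = 60 / T` seconds — and
records the times at which the subject's repeated movement (a head bob, an
arm chop) reaches its lowest point. `beatsync` treats those event times as
given; extracting them from video or audio is out of scope.

Every analysis starts from the **relative phase** of each movement: the
event is matched to its nearest beat onset and its timing error is expressed
in degrees of the beat cycle,

$$\theta_i = 360\,\frac{t_{\mathrm{event},i} - t_{\mathrm{beat},i}}{dt},
\qquad \theta_i \in (-180, 180].$$

Under this sign convention a movement that slightly *precedes* its beat — the
classic *negative mean asynchrony* of human tapping — has a small negative
phase. Note that the equation is sometimes printed with the opposite
difference (beat minus movement), which would make early movements positive
and contradict the usual reading of reported negative phases; the package
defaults to movement-minus-beat and exposes the flipped convention through
`analysis_config(phase_sign = "beat_minus_movement")`. An event exactly half
a period from two beats is assigned to the earlier one by default
(`nearest_beat_tie`); no convention is standard, and the choice only matters
on a measure-zero set. Events falling more than half a period outside the
grid are excluded and logged rather than force-matched.

Phase samples live on the circle, so the descriptives are circular: the
mean direction is the argument of the mean resultant vector
$\bar z = N^{-1}\sum_n e^{i\theta_n}$, the **vector length**
$\bar R = |\bar z| \in [0, 1]$ is the concentration (1 = all phases
identical, 0 = balanced dispersion), and the circular SD is
$\sqrt{-2\ln\bar R}$. `circular_mean()` refuses to return a direction when
$\bar R < 10^{-12}$ — the direction of a balanced sample is undefined and a
silent answer would hide that.

Per-trial tempo is reported in bpm. The default is the mean of the
instantaneous tempos `60 / interval` (with its SD likewise on the bpm
scale), because tempo variability is conventionally quoted in ±bpm; the
alternative `60 / mean(interval)` is available via
`analysis_config(tempo_method = "reciprocal_of_mean_interval")` and is the
better choice when intervals are noisy, since the mean of reciprocals is
Jensen-inflated by roughly `T · cv²`. Which definition a given report used is
rarely stated; both are first-class here. Subject-level aggregation follows
the conventional tabulation: linear averages of trial tempos and vector
lengths, circular average of trial mean phases, and a tempo SD pooled over
all of the subject's intervals at that tempo.

## The test battery

Three classical circular tests, all hand-implemented and oracle-tested
(type-I error at nominal level over $10^4$ Monte Carlo replicates; see
`tests/testthat/`):

* **Rayleigh test** of uniformity — significance operationalizes
  *entrainment* (phases are systematically related to the beat). The
  statistic is $z = N\bar R^2$; the p-value uses the standard higher-order
  series approximation in $z$ and $N$, clamped to $[0, 1]$, not the bare
  $e^{-z}$.
* **V-test** against a specified direction $\mu_0$ (here $0°$, the beat) —
  significance operationalizes *synchronization*: entrained **and** centred
  on the beat. $V = \bar R\cos(\bar\theta - \mu_0)$,
  $u = V\sqrt{2N}$, upper-tail normal.
* **Watson–Williams** F-test of equal mean directions across $k$ groups,
  with the usual $1 + 3/(8\hat\kappa)$ correction, $\hat\kappa$ estimated at
  the weighted mean of the group resultant lengths, and
  $df = (k-1, N-k)$ (stated explicitly in the output, since F-values are
  often reported without df). The test assumes concentrated samples; below
  a weighted mean resultant length of 0.45 the result carries a warning
  rather than an error, because real gross-movement phase data are often
  dispersed (trial vector lengths down to 0.02) and the test is still
  conventionally reported for them.

Von Mises concentration is estimated by inverting the Bessel ratio
$A(\kappa) = I_1(\kappa)/I_0(\kappa)$: the standard piecewise initial
approximation followed by Newton steps on exponentially scaled Bessel
functions, accurate to `1e-6` over the whole range and capped at
$\kappa = 10^5$ (numerically a point mass; the cap is what a sample of
identical phases produces instead of an infinite estimate).
`fit_kappa(r, n)` applies the standard small-sample bias correction only
when `n` is supplied and small; the internal callers (the Watson–Williams
correction, the window fits) use the plain ML inversion.

No multiple-testing correction is applied anywhere: the outputs are raw
p-values, documented as such.

## The sliding-window Monte Carlo simulator

To ask "how would a population of humans perform this task?", the simulator
builds an empirical generative model from real (or synthetic) trials:

1. **Screening.** Trials with mean vector length below 0.4 are removed
   (boundary kept) — incoherent trials carry no usable phase structure.
2. **Window fits.** The surviving trials at one tempo are pooled into
   overlapping windows of 4 consecutive chops (chops 1–4, 2–5, …; 22
   windows for 25-chop trials). Each window gets a normal fit to its
   inter-chop intervals and a Von Mises fit (circular mean + $\hat\kappa$)
   to its phases. Chop 1 has no preceding interval, so window 1 pools the
   intervals of chops 2–4 only — the alternative (dropping the window's
   first interval everywhere) changes nothing materially but must be pinned
   down. Windowing deliberately avoids assuming any parametric trend in
   phase or interval across the trial while still letting the simulation be
   non-stationary.
3. **Sequential generation.** Each simulated trial runs on a fresh 29-beat
   grid with the first onset at $t = 0$ (the extra beats absorb skipped
   beats). Chop 1's phase is drawn directly from window 1's Von Mises — it
   is an exact draw, so no rejection step is needed — and converted to an
   onset. Each later chop `n` draws an interval from the normal of *its*
   window, computes the implied phase against the nearest beat, and accepts
   it with probability equal to the window's Von Mises density normalized
   by its mode, $\exp\{\kappa_w[\cos(\theta - \mu_w) - 1]\}$; on rejection
   the *interval* is redrawn (the trial is never restarted). Negative
   proposed intervals are rejected outright. A per-chop cap (default
   10,000 attempts) turns an inconsistent fit — a point-mass interval
   pointing away from a point-mass phase — into an informative error.
4. **Cohort.** 10,000 trials of 24 chops per tempo; per-trial mean phase,
   mean interval (both in seconds and as mean instantaneous bpm — cohort
   tables that print "interval" on a bpm scale are a recurring source of
   confusion, so both are labelled), and vector length; aggregates with the
   circular mean over trial phases. `(models, rng_seed)` fully determine
   the cohort.

"The window for chop `n`" is genuinely ambiguous for overlapping windows.
The default takes the window whose *last* member is chop `n`
(`clamp(n - width + 1, 1, n_windows)`), i.e. generation is conditioned on
the most recent history; `sim_config(window_rule = "leading")` switches to
`clamp(n, 1, n_windows)`. Both reproduce the same overall structure; with
24-chop trials under the trailing rule the final (22nd) window is fitted
but never drawn from.

A robust emergent signature, useful as a sanity check: plotting per-trial
mean tempo against vector length yields a U-shape — trials whose tempo
wanders from the stimulus necessarily spread their phases — asserted in the
tests as a negative rank correlation between tempo error and vector length.

Observed values are located in a cohort two ways: a z-test treating the
10,000 per-trial statistics as approximately normal (phases compared on the
linear degree scale after wrapping — adequate while cohorts stay far from
the ±180° cut), and the distribution-free exceedance fraction (share of
simulated trials with larger |mean phase|, plus the signed variant).

## The synthetic study generator

`generate_study()` emulates the comparative design end-to-end so the whole
pipeline is testable without any data download: ten heterogeneous human
subjects plus one expert subject, each performing 4 trials at each of 112,
120 and 128 bpm (12 trials per subject), 25 beats per trial.

Generation is **beat-anchored**: each beat receives a phase
$\mu + d\,(k - \bar k) + \varepsilon_k$ and the event time is the beat
onset plus `phase/360 · dt`. This makes the ground-truth phase parameters
exact by construction, which is what parameter-recovery tests need. Three
consequences of this choice are worth spelling out:

* A systematic tempo bias `b` is *identical* to a linear phase drift: the
  generator realises it as a slope $d_b = -360\,b/(T+b)$ degrees per beat,
  which makes the expected performed tempo exactly `T + b`; centring the
  total drift on the trial midpoint keeps the expected trial circular mean
  at $\mu$.
* Event times are built from the *unwrapped* phase, so a subject drifting
  past half a cycle slides smoothly toward the neighbouring beat instead of
  teleporting backwards across the ±180° cut. Wrapped times would create
  spurious near-zero intervals. Strict monotonicity of event times is
  guaranteed for any drift (the wrapped increment is bounded), and a guard
  errors if a parameter combination ever violates it.
* With *independent* per-beat noise, interval variance is twice the phase
  variance — dispersed subjects would jitter absurdly (instantaneous tempos
  hundreds of bpm off). Real asynchronies wander slowly and are strongly
  autocorrelated, so each profile has a `phase_ar1` parameter: for
  $\rho > 0$ the noise is a stationary AR(1) Gaussian whose marginal spread
  is matched to the Von Mises resultant length $A(\kappa)$ (so
  concentration ground truth is preserved), and whose smoothness brings
  interval variability down to the realistic ±2–17 bpm range. At
  $\rho = 0$ (the default for `subject_profile()`) the noise is an exact
  independent Von Mises draw.

The default profiles are calibrated once, to the qualitative structure of
gross-movement beat keeping: human mean asynchronies centred near −16° with
wide between-subject spread (−60° to +25°), concentrations from near-uniform
to tight (trial vector lengths ~0.05–0.95), tempo biases within ±4 bpm; the
expert slightly fast (+0.5 bpm), clearly negative (−20°), drifting slightly
more negative within trials (−0.4°/chop), and more concentrated
($\kappa = 8$, trial vector lengths ~0.9) than nearly every human — so she
leads the rank tables on interval SD and vector length without dominating
every metric. What the generator does **not** emulate: reaction-time
transients at trial onset, missed-beat corrections, movement-amplitude
effects, and the very lowest published tempo SDs (±2.33 bpm), which require
smoother interval processes than beat-anchored noise can produce. Passing
recovery tests on this generator therefore validates the estimators and the
pipeline plumbing, not any claim about real subjects. An
`interval_walk` mode (intervals accumulated as truncated normals around
`60/(T+b)`, `interval_cv` controlling their spread) provides a
stress-test alternative in which phase is free to wander.

## Problem sizes and numerical choices

Test-suite simulation sizes are chosen to keep every Monte Carlo band at
≥ 4 binomial SEs: $10^4$ replicates for type-I error checks (absolute band
±0.01 around α = 0.05), $10^4$ trials per tempo for cohort-level recovery
(cohort circular mean within 3° of the generating mean), $10^5$ pooled
phases for the uniformity goodness-of-fit under zero-concentration windows
(α = 0.01, with wide interval noise to decorrelate successive phases), and
window-level self-consistency judged jointly across the 22 correlated
windows (bulk within 2 SE, all within 4 SE) rather than window-by-window.
Angles are degrees everywhere at module boundaries, radians only inside the
kernels; summary tables are written at 6 decimal places with explicit signs
on angle columns and round-trip bit-exactly at that precision.

## Known limitations

* The Watson–Williams test is used (with a warning) far outside its
  concentration assumptions when applied to dispersed human data — matching
  field practice, but p-values there deserve skepticism.
* The z-test's linear treatment of circular cohort means breaks down if a
  cohort straddles ±180°; no correction is attempted beyond wrapping.
* The simulator inherits the screening threshold (0.4) as a hard cutoff;
  cohorts fitted from very few surviving trials are valid but noisy, and
  the per-window observation counts in the output are the right thing to
  inspect.
* Performed-tempo defaults (mean instantaneous bpm) carry Jensen inflation
  for noisy subjects; comparisons across pipelines must pin down the tempo
  definition before comparing numbers.
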