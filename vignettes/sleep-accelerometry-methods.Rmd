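---
title: "Methods: from minute-level accelerometry to survey-weighted sleep parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from minute-level accelerometry to survey-weighted sleep parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`actisleep` estimates three objective sleep parameters — clock time of
sleep onset (CTSO), sleep duration and sleep efficiency — from
minute-level wrist-accelerometer summaries of the kind released by
national surveys (per-minute MIMS activity, a device wear/sleep
prediction, quality-flag counts), and carries them through design-based
estimation for a stratified two-PSU-per-stratum sample. This vignette
documents the model, the tunable parameters, the synthetic cohort used
for validation, and the numerical and design choices that were genuinely
open.

## 1. Preprocessing rules

A minute is marked missing if any of three conditions holds: the MIMS
value is the `-0.01` invalid-data sentinel, the wear prediction is
non-wear, or the quality-flag count is positive. All other minutes pass
through untouched, and the masking is idempotent.

Three thresholds govern what happens next (all configurable through
`pipeline_config()`; defaults in parentheses):

* **minimum missing interval** (60 min): only maximal missing runs at
  least this long are treated as imputable intervals. Shorter missing
  runs are set to 0 — a deliberate reading of the convention that masked
  values are "missing, i.e. a value of 0": isolated flagged minutes
  contribute no activity, while long device-off blocks are
  reconstructed. The interaction between "set to 0" and "impute" is not
  fully determined by the data documentation; this 60-minute split is our
  resolution and is exposed as a parameter for sensitivity analysis.
* **valid wear day** (strictly > 960 min = 16 h of wear): "more than
  16 h" is read literally as a strict inequality; 960 minutes is invalid,
  961 is valid. Wear is what the wear-prediction flag asserts (the flag,
  not the value, encodes wear; an "unknown" prediction counts as wear —
  only non-wear is a documented missingness trigger — and this treatment
  is flagged for sensitivity analysis).
* **imputation eligibility** (≥ 4 valid days per subject).

Imputation is deliberately simple and deterministic by default:
`minute_profile` replaces a missing minute by the subject's mean
non-missing value at the same minute of day across their valid days,
falling back to the day-level mean (logged) when a minute of day has no
donors. A stochastic `zip_model` variant draws from a zero-inflated
log-normal fit to the same donor profile under a seed. We do not
reproduce any particular published imputation package's internals; the
profile method keeps the pipeline reproducible bit-for-bit, and on
synthetic data its effect on downstream duration estimates is small
relative to the recovery tolerances (regression-tested).

Partially recorded days at device start/end receive no special handling:
the wear-day rule decides their validity.

## 2. The two-state sleep/wake HMM

Per subject, the concatenated multi-day activity series is transformed to
$y_t = \log(1 + x_t)$ (monotone, variance-stabilising, 0 maps to 0) and
modelled as a two-state Gaussian hidden Markov model: initial
distribution $\pi$, transition matrix $A$, emissions
$y_t \mid S_t = k \sim N(\mu_k, \sigma_k^2)$. Assumptions worth stating:

* **Two states.** Sleep vs wake only; naps and quiet wakefulness are not
  distinguished from the main states. "Awake and not moving" will look
  like sleep to any actigraph; that limitation is inherited from the
  measurement, not the model.
* **Gaussian emissions on the log scale.** MIMS is positive and
  right-skewed; log(1+x) makes a two-component Gaussian mixture with
  Markov persistence a reasonable working model. The emission family of
  the original research code this design parallels is not published in
  detail; equivalence is not claimed.
* **One model per subject over the whole week** (not per day): the week
  shares one behavioural regime, and 10,080 minutes support stable EM.

Fitting is Baum–Welch EM with scaled forward–backward recursions in
compiled code (no underflow for week-long series; per-minute emission
densities are max-shifted before exponentiation so a single outlier
cannot zero both states). Numerical choices:

* **Initialisation**: `quantile_split` (deterministic; state means at the
  25th/75th percentiles of y, common sd = sd(y)/2, self-transitions
  0.95) is the default; a seeded k-means initialisation is available.
  Both converge to the same model up to relabeling on well-separated
  data (tested).
* **Convergence**: relative log-likelihood increase < 1e-6, max 200
  iterations. The likelihood trace is retained and its monotonicity
  asserted in tests.
* **Label switching**: the sleep state is defined post hoc as the
  lower-mean state, which resolves the EM label ambiguity
  deterministically.
* **Degenerate input**: a (near-)constant series cannot support two
  emission components; the fit is flagged and the subject is skipped by
  the scorer rather than given arbitrary labels.
* **Decoding**: posterior (local) decoding by default — each minute is
  sleep iff its smoothed marginal sleep probability exceeds 0.5, with an
  exact tie decoding to wake (a stated convention; ties occur only on
  contrived symmetric inputs). Viterbi is available; local decoding is
  the default because the SPT scorer consumes per-minute sleep mass, not
  a jointly optimal path.

Correctness is anchored by an independent oracle: an exhaustive
enumeration of all $2^T$ state paths (refused above T = 16) must agree
with the forward recursion to 1e-10 across random models, and EM must
recover a known well-separated generating model (emission means within
0.1, transition probabilities within 0.05 on a simulated week).

## 3. Nightly sleep parameters

The analysis unit is the noon-to-noon "sleep day". Within each window:

1. sleep runs separated by wake runs shorter than `merge_gap_max`
   (60 min) are merged into candidate blocks;
2. the longest block is the SPT window (ties break to the earliest
   start); blocks start and end in sleep by construction, so no wake
   bout touches the SPT boundary;
3. CTSO = 12 + (SPT start in minutes after noon)/60, a continuous
   12–36 h clock in which 11 pm is 23 and 1 am is 25;
4. wake bouts are maximal wake runs strictly inside the window — each
   shorter than the merge gap by construction;
5. sleep duration = SPT duration − summed bout duration, and
   sleep efficiency = sleep duration / SPT duration (the denominator is
   the SPT window, not time in bed, which accelerometry cannot see).

The merge tolerance is the one genuinely free parameter here: a sleep
period that "contains wake bouts" requires some rule for what still
counts as the same period. We use 60 min — the same scale as the
missing-interval rule — and expose it (`merge_gap_max`). Nights with SPT
duration < 3 h or > 15 h are invalid; subjects with fewer than 3 valid
nights are excluded. A window with no sleep yields an invalid night, not
a zero-duration one.

Windows at the recording edges are partial. A night in a partial window
is scored only if its SPT lies strictly inside the recorded region;
otherwise a truncated SPT would masquerade as short sleep. Weekend
nights are those anchored on a Friday or Saturday noon — the sleep
episode precedes a school/work-free morning — so a 7-day recording
always contains both classes.

## 4. Survey estimation

* **Weights**: two combined 2-year cycles → 4-year weight = half the
  2-year exam weight. Single-cycle inputs pass through unhalved only
  under an explicit flag, with a warning.
* **Means and totals**: Horvitz–Thompson ratio mean; Taylor-linearized
  variance from between-PSU contrasts within strata (with-replacement
  PSU approximation). A stratum left with a single PSU contributes its
  deviation from the grand mean of PSU totals (the common survey-software
  "centered" lonely-PSU rule), with a warning.
* **Quantiles**: lower inverse of the weighted empirical CDF,
  $q(p) = \min\{x : F_w(x) \ge p\}$ — exactly invertible, invariant to
  weight rescaling, type-1 under equal weights; computed within nine
  standard age groups (6–13 … ≥ 76).
* **Trend models**: survey-weighted least squares of each sleep
  parameter on a quartic polynomial in scaled age $s = (\text{age}-45)/40$
  plus sex (reference male) and race (reference NH White), with optional
  sex×age and race×age interaction blocks. Age is scaled before raising
  to powers because age⁴ in raw years conditions the normal equations
  badly; the synthetic generator's curves are defined on the same basis,
  so fitted coefficients are directly comparable with generator
  coefficients. Fitted curves are exported on an age 6–85 grid per
  sex/race for plotting.
* **Small-sample covariance**: the plain linearized sandwich is biased
  down when the PSU count is modest relative to the parameter count
  (with 60 PSUs and ~13 parameters we measured 4-df interaction Wald
  size near 8% on an independent null simulation). `svy_lm` therefore
  applies the Bell–McCaffrey CR2 leverage adjustment to PSU score
  contributions by default (`small_sample = "none"` restores the
  classical estimator), and block tests use the Korn–Graubard adjusted
  Wald F, $W(\mathrm{df}-d+1)/(\mathrm{df}\,d) \sim F(d, \mathrm{df}-d+1)$
  with df = #PSUs − #strata. With both in place the same null simulation
  shows 4-df size near 5–6% and 1-df size near 4.5–5%.
* **Efficiency quartiles**: sleep efficiency is strongly left-skewed, so
  the linear trend is confirmed by survey-weighted proportional-odds
  regression on quartiles cut at the weighted quartiles of the analysis
  sample. The fit uses the MASS::polr sign convention
  ($\mathrm{logit}\,P(Y \le k) = \zeta_k - x'\beta$); the design-based
  covariance comes from linearizing the weighted score equations over
  PSUs. Significance is reported at 0.05 throughout.

## 5. The synthetic cohort

The generator (`cohort_config()` / `simulate_cohort()`) emulates the
statistical structure the pipeline assumes, with known truth:

* ages uniform on 6–85 (real surveys top-code age and oversample some
  bands; top-coding is not emulated), sex Bernoulli(½), race in four
  groups at realistic national proportions (~64/11/10/14%);
* per-night true onset and duration follow quartic age curves on the
  shared scaled-age basis, frozen package defaults shaped like published
  national estimates (onset latest near age 24, duration minimal near
  age 41), plus additive female shifts (+0.076 h onset, +4 min duration)
  and race offsets, night-level Gaussian onset jitter (sd 0.75 h), and
  weekend delays (+35 min onset, +70 min wakeup on Friday/Saturday
  nights);
* a per-night target efficiency (declining linearly with age, with race
  offsets) is realised by carving a Poisson number of wake bouts out of
  the sleep window, each bout capped at 45 min so a true sleep period is
  never split by its own bouts under the 60-min merge rule;
* minute-level MIMS is emitted log-normally per state
  (log(1+x) ~ N(0.4, 0.4) asleep, N(2.8, 0.6) awake — well separated,
  as wrist MIMS is in practice), then corrupted by non-wear blocks
  (probability 0.08/day, 120 min), quality flags (0.002/min), `-0.01`
  sentinels (5e-4/min) and "unknown" wear predictions (0.001/min);
* the survey design assigns subjects to 30 strata × 2 PSUs (emulating
  two combined 2-year cycles of ~15 masked variance strata each) with
  weights inversely proportional to an age-band sampling rate.

What the generator does *not* emulate — circadian dynamics, naps and
secondary sleep periods, within-PSU correlation, informative
missingness, device artefacts beyond the flag types above — bounds what
passing tests show about real data: they validate the estimators and
the scoring logic under the stated model, not the behavioural realism of
any given survey.

## 6. Problem sizes and tolerances used in validation

The test suite and the acceptance script use sizes chosen to exercise
the method at meaningful scale while staying desk-runnable: a
300-subject, 7-day cohort (≈ 3.0 million subject-minutes) for end-to-end
recovery (per-subject MAE targets: < 10 min onset and duration, < 0.02
efficiency); 200 truth-level replicates of 300 subjects for coverage of
the generator's quartic-age coefficients by ±2 design-based SEs; 500
replicates of 350 subjects for the type-I error of the sex×age
interaction Wald test under a null generator; 100 random model/series
draws (T ≤ 12) for the forward-vs-enumeration identity at 1e-10; and a
simulated week from a known model for EM recovery. All replicate seeds
derive from a single base seed.

## 7. Known limitations

* Accelerometry cannot distinguish motionless wakefulness from sleep;
  efficiency and duration are likely optimistic, and the SPT-window
  denominator makes efficiency higher than time-in-bed definitions.
* Sleep-onset latency and nap structure are out of scope (no diary, one
  main sleep period per noon-to-noon day).
* The proportional-odds fit assumes proportionality across quartile
  cuts; it is used as a confirmation of the linear model's signs, not as
  the primary estimate.
* Weights are treated as fixed; imputation-aware variance and
  non-response adjustment construction are out of scope.
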