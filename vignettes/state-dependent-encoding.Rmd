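---
title: "Dissociating task engagement and arousal in sensory encoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating task engagement and arousal in sensory encoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilstate)
```

## The problem

When an animal switches from passively hearing sounds to actively
performing a detection task, sensory neurons change their firing. But task
engagement never comes alone: arousal, indexed by pupil diameter, rises in
active blocks too. Any "task effect" measured as an active-vs-passive
contrast is therefore confounded with arousal, and any "arousal effect"
with task. This package implements a state-dependent encoding model that
dissociates the two by regressing single-trial firing on both state
variables at once and asking, via cross-validated shuffle controls, what
each variable explains *uniquely*.

## The model

For each unit, the single-trial firing rate at time $t$ (20 Hz bins)
during reference-sound presentations is predicted from the unit's mean
evoked response $r_0(t)$ (the stimulus-specific PSTH), its spontaneous
rate $s_0$, binary task engagement $b(t)$ (1 in active blocks) and
normalized, lagged pupil diameter $p(t)$:

$$
r_{\mathrm{full}}(t) \;=\; s_0\,F_d\!\big[d_0 + d_p\,p(t) + d_b\,b(t)\big]
\;+\; r_0(t)\,F_g\!\big[g_0 + g_p\,p(t) + g_b\,b(t)\big]
$$

The $d$-path shifts the baseline (DC offset); the $g$-path scales the
evoked response (gain). Six coefficients are fitted
($d_0, d_p, d_b, g_0, g_p, g_b$); $F_d$ and $F_g$ are fixed saturating
nonlinearities (below). Control models shuffle one or both state
regressors across trials:

* **null** — both shuffled; reduces (at the neutral coefficients) to
  $s_0 + r_0(t)$;
* **task-only** — pupil shuffled;
* **pupil-only** — task shuffled.

Variance uniquely explained by a state variable is the difference in
cross-validated $r^2$ (squared Pearson correlation between held-out
prediction and observed rate) between the full model and the partial
model in which that variable was shuffled. The same subtraction applied
to modulation indices yields task-unique and pupil-unique MI components.

### The sigmoid and its neutral point

The summed state signal passes through a Gompertz ("difference of
exponentials") sigmoid $F(x) = B + A\,e^{-e^{-k(x - x_0)}}$ with fixed
constants $(B, A, k) = (0, 2, 1)$ and $x_0$ solved once so that
$F(1) = 1$. The choice of shape is a design decision: any fixed monotone
saturating nonlinearity with a neutral pass-through point reproduces the
null-model reduction exactly, which is the property the analysis relies
on. We implement $F$ algebraically as $A\,(1/A)^{\exp(-k(x-1))}$, for
which `F(1) == 1` holds *exactly* in floating point, so evaluating the
full model at the neutral coefficients is bitwise identical to
$s_0 + r_0(t)$. An identity-nonlinearity test mode
(`sigmoid_constants(identity = TRUE)`) removes the nonlinearity entirely;
it is used in the noiseless parameter-recovery tests where exact optima
are known.

## Preprocessing conventions

* **Binning.** All signals live on one 20 samples/s grid. Epochs are
  half-open `[start, end)` in seconds; a bin belongs to an epoch iff its
  left edge lies inside. This makes aggregation unambiguous at block,
  trial, and stimulus boundaries.
* **Pupil lag.** Pupil is shifted by 750 ms (15 bins) before use as a
  regressor, reflecting the lag between pupil-linked state and neural
  activity. The leading samples hold the first value so all signals keep
  equal length (configurable).
* **Pupil normalization.** The regressor is pupil divided by its session
  maximum; raw diameter units are retained for reporting.
* **Reference responses.** $r_0$ averages only passive and active *hit*
  trials, and presentations overlapping a target are excluded, so reward
  events and behavioral errors do not contaminate the sensory average.
* **Spontaneous rate.** The study never pins down the $s_0$ estimation
  window; we use the mean rate over 0.35 s pre-trial windows plus
  inter-stimulus gaps, excluding 0.2 s after each stimulus offset to
  avoid offset responses. Both windows are arguments of
  `extract_reference_responses()`.
* **Pupil median split.** Large vs small pupil is a median split over
  per-presentation mean pupil (per-bin splitting is the alternative the
  source leaves open); ties go to "small" — deterministic and documented.

## Fitting and inference

* **Cross-validation.** 20 folds over interleaved trials: each fold's
  model is fit on 95% of trials and predicts the held-out 5%, so the
  concatenated prediction covers every bin exactly once. The procedure is
  described as "nested" in the source material, but with no fitted
  hyperparameters the inner loop is vacuous; we implement plain 20-fold
  CV and say so. $r_0$ and $s_0$ are re-estimated from each training fold
  (the conservative leakage-free choice).
* **Optimizer.** Bounded L-BFGS-B on mean squared error with an analytic
  gradient, coefficients bounded in $[-10, 10]$. Fold 1 takes the best of
  three starts (the neutral point $d_0 = g_0 = 1$, others 0, plus two
  seeded jitters); later folds warm-start from the previous fold's
  optimum, since adjacent folds share 95% of their data. Non-converged
  fits are retried from seeded jitters and flagged if they never
  converge.
* **Ridge tie-break.** Once a sigmoid saturates, whole directions of
  coefficient space become MSE-equivalent plateaus (a huge $d_p$ with a
  compensating $g$-path predicts the same rates as a modest one). A
  negligible ridge toward the neutral point
  ($10^{-6}\,\mathrm{var}(y)\,\lVert\theta - \theta_{\mathrm{neutral}}\rVert^2$)
  tie-breaks these plateaus without measurably biasing identified
  coefficients (noiseless recovery stays within $10^{-3}$ of truth).
* **Identifiability in recovery tests.** When $r_0$ is re-estimated from
  state-modulated data, the PSTH absorbs the average state effect
  ($\hat r_0 = s_0\,\overline{F_d} + r_0\,\overline{F_g}$), so generative
  coefficients are *not* the optimum of the refit pipeline even without
  noise. Parameter-recovery tests therefore pin $r_0/s_0$ at ground truth
  (`truth_refset()`), which is the controlled setting in which the
  question "does the optimizer recover the coefficients?" is well posed.
  The production pipeline always re-estimates.
* **Shuffle granularity.** State signals are shuffled by permuting whole
  per-trial blocks among trials of equal length, preserving within-trial
  autocorrelation and the marginal distribution (the source says only
  "shuffled in time"; per-bin shuffling would destroy autocorrelation and
  make the null too easy).
* **Jackknife t-test.** Model comparisons use leave-one-fold-out
  estimates of the difference in Pearson correlation with the observed
  rate; the t statistic is the mean difference over its jackknife
  standard error ($\frac{n-1}{n}$ inflation), two-sided with $n-1$
  degrees of freedom. Identical predictions give $p = 1$ by convention.
* **Classification.** Units are gated on the full-vs-null contrast
  ($p < 0.05$), then labeled `task_only` / `pupil_only` / `both` by the
  two unique-variance contrasts, or `ambiguous_state` when neither is
  individually significant.

## Modulation indices

$\mathrm{MI} = (\bar r_\alpha - \bar r_\beta)/(\bar r_\alpha + \bar r_\beta)$
between mean predicted rates over the 0.75 s stimulus windows of two
condition classes: active/passive (AP), large/small pupil (LS), or first
vs second passive block (P1P2). Predictions are rectified at 0 first so
the $[-1, 1]$ bound holds; $0/0$ is defined as 0. MI is computed from
model predictions (a raw-rate MI exists for diagnostics); unique
components come from the exact subtractions
$\mathrm{MI}^{\mathrm{task\,unique}} = \mathrm{MI}^{\mathrm{full}} -
\mathrm{MI}^{\mathrm{pupil\,only}}$ and symmetrically for pupil.

For population summaries, each unit's (task-only, task-unique) pair is
multiplied by the sign of the pair mean ("sign normalization", ties to
$+1$) so magnitude comparisons are direction-agnostic; the percent
reduction is $1 - \overline{\mathrm{unique}}/\overline{\mathrm{only}}$ on
the normalized values.

**A structural note on the reduction's limits.** A pupil-only synthetic
population shows a reduction near 100%. A task-only population does *not*
approach 0% under realistic conditions: the paradigm itself couples pupil
to task (pupil is larger in active blocks), so the pupil regressor can
stand in for part of the task regressor, and the task-population
reduction floors at roughly the share of $b$'s variance explainable by
$p$ (about 35% at the calibrated pupil overlap, consistent with
point-biserial theory). Both endpoints can only be reached jointly in the
unrealistic limit of task-independent pupil. The acceptance suite
therefore checks the monotone ordering of the reduction in the
pupil/task effect-size ratio and the separation of the endpoints, not
literal 100%/0% values.

## Population statistics

* **Hierarchical bootstrap.** Units from one array recording are not
  independent; each of the 10,000 iterations resamples sites with
  replacement, then units within each sampled site. Two-sided location
  p-values are $2\min(\Pr(\theta^* \le 0), \Pr(\theta^* \ge 0))$, floored
  at $1/n_{\mathrm{iter}}$ and labeled `"< 1/n_iter"` when no crossing
  occurs; we report the floor implied by the iteration count rather than
  any finer value. Two levels (site, unit) are resampled; the animal
  level is out of scope. On a *flat* exchangeable null this estimator is
  conservative by construction (site resampling over-disperses the
  bootstrap distribution); it is calibrated in the presence of genuine
  site-level variance, which is the regime it exists for — the
  calibration test simulates that matched null.
* **Correlation test.** The point estimate is the plain Pearson $r$ over
  all unit/target pairs; its p-value comes from the hierarchical
  bootstrap distribution of $r$ against 0.
* **Independence permutation test.** Whether units with both task- and
  pupil-unique effects are over-represented: one flag vector is permuted
  across units; the one-sided (enrichment) p is the fraction of
  permutations with at least the observed joint count. For $n \le 8$
  units all $n!$ permutations are enumerated exactly; otherwise random
  permutations are sampled.

## Behavioral metrics

Hit rate is hits/(hits+misses) over target presentations; the false-alarm
rate is per *reference*: one FA for the licked reference of an FA trial
and one correct rejection per completed un-licked reference, so FAR is
the proportion of reference stimuli that elicited a lick. A lick after
the 0.1–1.5 s response window with no earlier lick scores a miss
(documented convention). $d' = z(\mathrm{HR}) - z(\mathrm{FAR})$ with
rates clipped to $[1/2n,\, 1 - 1/2n]$ before z-scoring — the standard
correction for perfect rates, which the source leaves unspecified
(log-linear correction would be the config alternative).

## Tuning metrics

STRFs are estimated by reverse correlation (lagged cross-correlation of
mean-subtracted rate with each spectrogram channel, normalized by channel
variance); no second-order stimulus-autocorrelation correction is applied
because the intended stimuli are near-white ripple ensembles. BF is the
center of mass, on the log-frequency axis, of the positive part of the
first singular vector of the STRF, sign-aligned so its largest-magnitude
coefficient is positive. The response SNR definition used in the source
is delegated to a reference we do not reproduce; we substitute a
split-half estimator — the Spearman–Brown-corrected correlation of two
half-PSTHs, averaged over random splits and floored at 0 — and document
it as a substitution. The unfloored mean is attached as an attribute
because flooring induces a positive bias under the null, which matters
for calibration checks.

## The synthetic-session generator

`generate_session()` emulates the statistical structure the analysis
assumes, with stored ground truth for every quantity:

* **Scaffold.** Blocks P1–A1–P2 (configurable), 60 trials/block by
  default; each trial is 2–5 reference sounds (0.75 s, 0.7 s gaps) whose
  count follows a flat hazard (stopping probability 1/3 after each of the
  2nd–4th references, forced at the 5th), followed by a target with a
  0.1–1.5 s response window; 2.5 s inter-trial intervals.
* **Behavior.** Each completed reference elicits a false-alarm lick with
  probability 0.05 (the trial truncates at the lick); trials reaching the
  target are hits with probability 0.85, else misses. Passive trials
  carry CR outcomes.
* **Pupil.** An Ornstein–Uhlenbeck process (time constant 15 s,
  stationary SD 6 diameter units) reverting to a block baseline
  (passive 40, active 48), plus a gamma-shaped dilation at each trial
  onset (peak 1 s post-onset; amplitude 6 in active, 1.5 in passive
  blocks). The active shift of 8 against a within-block SD of 6 gives
  broadly overlapping passive/active pupil distributions with the active
  mean consistently larger — pupil is an informative but imperfect proxy
  for task, which is precisely the regime the dissociation analysis is
  for. A `p2_baseline_shift` knob lets arousal persist into the
  post-behavior passive block for persistence analyses; a flag for
  passive-like pupil on miss trials exists and defaults to off.
* **Spiking.** Per-stimulus PSTHs are smooth random bumps scaled to
  20 spikes/s, spontaneous rate 5 spikes/s; the noiseless rate is the
  state-model forward pass itself (the generator and the fitter share one
  code path, so evaluating the stored parameters on the stored latents
  reproduces the stored noiseless rates bitwise). Observed rates are
  Poisson counts per 50 ms bin divided by the bin width (Gaussian and
  noise-free options exist). Default effect types cycle
  task/pupil/both/none with coefficients 0.5 (task), 0.75 (pupil),
  0.5/0.4 (both) — chosen once so that generative MI values match the
  scale reported for real units (task MI around 0.15–0.2, pupil MI small,
  ~0.05).

**What the generator does not emulate:** spike-sorting artifacts and unit
isolation drift, blinks and pupil video artifacts, non-stationary
arousal beyond the OU process, stimulus acoustics (no TORC waveforms —
tuning analyses use separate white-noise spectrograms), reaction-time
structure, and between-animal variability. Passing tests therefore show
that the analysis recovers what it assumes when its assumptions hold;
they cannot certify behavior under artifacts the generator omits.

## Problem sizes

The test suite and acceptance script choose sizes that keep full runs in
minutes while leaving every estimate comfortably resolved: recovery runs
use 50 units at ~300 included presentations each; specificity runs 50
replicate sessions with one pupil-only and one task-only unit each;
calibration runs 200 null replicates (bootstrap at 1,000 iterations for
the calibration loop, 10,000 — the study's value — everywhere else); the
workflow scripts under `analysis/` simulate 4 sites of 4 units at 15
trials/block as a compact end-to-end demonstration.

## Known limitations

* The DC-path coefficients are weakly identified when $s_0$ is small
  relative to the evoked response; their jackknife standard errors are
  honest about this (they get large), but point estimates should be read
  with that in mind.
* With 20 trials/block sessions and realistic Poisson noise, pupil-only
  units frequently fail the overall state gate (classified `none`);
  dissociation statements are about specificity (not being called
  `task_only`), not about power.
* MI values from cross-validated predictions inherit fold-to-fold
  coefficient noise; population summaries should aggregate at least ~8
  unit/target pairs before interpreting a reduction percentage.
* The hierarchical bootstrap p-value is conservative when site-level
  variance is absent.
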