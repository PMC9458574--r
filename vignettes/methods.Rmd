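---
title: "Models and methods behind pupilexplore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pupilexplore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilexplore)
```

## The scientific question

In a two-alternative probabilistic learning task one option pays off on 70%
of trials and the other on 30%. Once a participant has learned this
contingency, occasionally choosing the objectively worse option anyway is
*directed exploration*: a deliberate, information-seeking violation of the
acquired utility model. `pupilexplore` implements the full analysis chain
used to characterize such choices behaviorally (response-time slowing) and
physiologically (phasic pupil dilation), together with a synthetic-session
generator that carries the statistical structure the analysis assumes, so
that every stage can be tested against ground truth.

The package distinguishes four *choice types*, labeled by the
(previous, current, next) choice triplet within a block:

| label  | triplet              | reading                          |
|--------|----------------------|----------------------------------|
| HP     | A → **A** → A        | stable exploitation              |
| preLP  | A → **A** → DA       | the trial before an exploration  |
| LP     | A → **DA** → A       | the exploratory choice itself    |
| postLP | DA → **A** → A       | the return to exploitation       |

(A = advantageous, DA = disadvantageous; any other pattern, and block-edge
trials, stay unclassified.) Labels are assigned separately inside
*after-learning* periods (trials after the learning criterion is met) and
inside unlearned (*no-learning*) blocks.

## The learning criterion

A block counts as learned at the first trial `t` such that trials
`t-3 … t` are all advantageous **and** the advantageous fraction from
`t+1` to the block end is at least 65%. The run-of-four requirement has
chance probability $(1/2)^3 = 12.5\%$ given a first advantageous choice;
the 65% threshold corresponds to the exact binomial tail
$P(X \ge \lceil 0.65 n \rceil)$, which for $n = 30$ and $p_0 = 0.5$ is
`r round(binomial_tail(30, 0.65, 0.5), 4)` — just at the 5% margin. Both
helpers (`run_probability()`, `binomial_tail()`) compute these quantities
exactly.

Two conventions the criterion's verbal statement leaves open are fixed
here and enforced identically in the implementation and in its
brute-force test oracle:

* when the after-period of an early run falls below 65%, later runs of
  four are tried in order (the earliest qualifying run defines the
  criterion point);
* a run of four that ends on the last trial of the block leaves an empty
  after-period, which satisfies the threshold vacuously.

## Pupil preprocessing

The chain mirrors standard pupillometry practice for a 1 kHz area signal:

1. **Artifact detection.** A sample is artifactual when it is missing or
   belongs to an adjacent pair whose absolute first difference exceeds
   10 pixels (strictly; both pair members are flagged). Flagged samples
   merge into runs; runs separated by fewer than 2 valid samples are
   merged before classification so that interpolation never bridges a
   flickering gap. Runs of at most 350 ms are *short*, longer ones *long*.
2. **Repair or flag.** Short runs are linearly interpolated between the
   nearest valid neighbors; long runs, and any run touching the recording
   boundary, stay invalid.
3. **Binning.** Consecutive 50-ms bins (20 points per second), each the
   arithmetic mean of its 50 samples; a bin containing any invalid sample
   is invalid rather than partially averaged.
4. **Session-wide z-scoring.** Within each subject, over all retained bins
   of all five blocks jointly. The session-wide mean acts as one common
   baseline for every condition and time point; no pretrial subtraction is
   applied on the main path, because with intertrial intervals shorter
   than the pupil response the pretrial baseline is contaminated by the
   previous trial's dilation (the carryover effect). Samples lost to long
   artifacts are excluded from the reference statistics (a sensitivity
   switch in `zscore_pupil`'s input preparation).
5. **Epoch extraction.** Response-locked epochs of 70 bins covering
   −1,000…2,500 ms relative to the button press (bins whose centers fall
   in the half-open window). An epoch is excluded when a long artifact
   overlaps the wider −2,000…3,000 ms window, or — with reason `extreme_z`
   — when any of its bins deviates from zero by strictly more than 3 SD
   (an epoch-mean variant is available via `extreme_rule`).
6. **Trial measures.** Mean z over the analysis window, over the three
   functional subintervals (−400…0, 0…1,000, 1,000…2,200 ms), the
   pretrial baseline (−300…0 ms before fixation onset), and a
   baseline-corrected variant (epoch minus pretrial baseline). All
   interval averaging uses bins whose centers fall in half-open
   `[start, end)` windows, so the default main window spans exactly
   52 bins.

## The analysis window is data-derived

Rather than fixing the averaging window a priori, the pipeline analyzes
each of the 70 epoch bins independently with the model

```
z ~ ChoiceType + (1|Subject) + (1|BlockNumber) + (1|ReinforcementScheme)
```

computes the Tukey-adjusted contrasts of pre-LP, LP and post-LP against
HP, corrects each contrast's 70 p-values with the false discovery rate at
q = 0.05 (Benjamini–Hochberg by default; Benjamini–Yekutieli behind the
`fdr` switch, and the flavor is recorded in every output), and takes per
contrast the maximal contiguous significant span containing the response
(0 ms). The selected window is the intersection of the three spans; if a
contrast has no qualifying span the configured fallback window
(−400…2,200 ms) is used instead.

## Mixed models, selection, contrasts

All trial-level analyses use linear mixed models with crossed random
intercepts for Subject, BlockNumber (position 1–5) and
ReinforcementScheme (the five gain/loss point schemes), REML-fitted via
lme4. The full fixed part is
`ChoiceType * PreviousFeedback * Learning`; backward selection
(`step_down`) first removes random intercepts whose restricted
likelihood-ratio test is nonsignificant — using the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ appropriate for a variance
component on the boundary — then iteratively removes the nonsignificant
fixed term with the highest type-III p-value, never removing a main
effect while an interaction containing it survives. Type-III F tests use
the Satterthwaite denominator-df approximation.

Pairwise comparisons are estimated marginal means with equal weights over
the other factors and Tukey (studentized-range) adjustment. Denominator
df for contrasts are Satterthwaite by default; a documented large-sample
(infinite-df) setting, `df_method = "asymptotic"`, exists for situations
where the model is fitted on thousands of trials and the two
approximations coincide numerically while the Satterthwaite gradient
computation dominates runtime. The per-bin pointwise models default to
this large-sample setting for exactly that reason (their df are in the
thousands); the main condition tables default to Satterthwaite.

Correlations between per-subject quantities (share of LP choices,
Eq.-style `p_da = n_da / (n_da + n_a)`, number of gains, LP−HP
differences in RT-z and late-window pupil z) use Pearson's r with a
two-sided permutation test: `p = (1 + #{|r*| ≥ |r|}) / (1 + n_perm)` with
20,000 reshuffles by default; when `n! ≤ n_perm` the test enumerates all
orderings and is exact. Subjects with at most one LP choice are excluded
from the LP-related correlations.

## What the synthetic generator emulates

The generator produces, per subject, five 40-trial blocks with the task's
event timing (150-ms fixation; stimulus until the button press; feedback
for 500 ms after a 1,000-ms delay; flat 700–1,400-ms intertrial
interval), outcome schedules that realize the 70/30 contingency with
exact per-block counts (independent Bernoulli draws behind
`schedule_method = "bernoulli"`), and a choice process with a delta-rule
value learner (rewards coded ±1), softmax choice, a win-stay/lose-shift
blend, and — once the internal preference exceeds a threshold —
deliberate disadvantageous choices at a configurable rate. Ground-truth
columns (the preference trajectory, the deliberate-exploration flag, the
generating condition of every trial) are retained so recovery tests never
depend on the agent's realism.

Defaults were chosen once to land in the neighborhood of the descriptive
statistics typical for this task: with `agent_params()` defaults,
roughly three quarters of blocks reach the learning criterion around
trial 11, the after-learning disadvantageous share is ≈16–18%, and a few
subjects in a hundred never learn (a per-subject Beta-distributed
disengagement propensity, mean 0.25, generates unlearned blocks and those
never-learners). Two behaviors of the stationary agent are known to
deviate from human data and are deliberate simplifications: unlearned
blocks are played near-randomly, so their disadvantageous share (≈45%)
is higher than typically observed, and the delta rule couples switches to
preceding losses somewhat more strongly than humans do. Passing tests on
this generator therefore demonstrate the correctness and power of the
*analysis*, not the realism of human exploration itself.

Response times are lognormal,
`rt = rt_base_ms × multiplier(condition) × exp(σ Z)`, with condition
multipliers mirroring the qualitative pattern of this task (after
learning: LP slowest at 1.4, HP fastest at 1.0; no-learning conditions
intermediate and flat).

The 1 kHz pupil signal is additive:

* a constant baseline (camera-pixel area units);
* a **hippus-like oscillation** (default 60 px at 0.47 Hz, random phase):
  the dominant variance component. Its period is much shorter than the
  averaging windows, so it contributes almost nothing to trial-level
  measures, but because it is a bounded waveform it keeps the z-scored
  signal's excursions well inside ±3 SD — on artifact-free data the 3-SD
  epoch rule then fires only on genuine artifacts, which is the intended
  semantics of that rule;
* a slow tonic drift (three sinusoids with periods of 1–5 minutes);
* a stimulus-locked light-reflex dip;
* a response-locked phasic kernel
  $h(t) = (t/t_{max})^s e^{s(1 - t/t_{max})}$ (unit peak at
  $t_{max} = 930$ ms, shape $s = 10.1$ — the canonical pupil-response
  parameterization), scaled by the trial condition's amplitude. The
  kernel outlasts the intertrial interval, so adjacent trials superpose
  and carryover into the next pretrial baseline emerges naturally;
* smooth measurement noise (white on a 40-ms knot grid, linearly
  interpolated), so adjacent-sample derivatives stay far below the
  10-pixel artifact threshold.

Artifacts are injected on top: blinks as invalid runs with configurable
durations and spikes as short >10-pixel jumps, both with a ground-truth
log against which the detector is tested (recovery within ±1 ms).

`calibrate_amplitude_map()` converts requested condition differences on
the z scale into pixel amplitudes, using the closed-form mean of the unit
kernel over the analysis window and a short calibration simulation of the
session-wide binned SD. This is how parameter-recovery studies inject,
e.g., an LP−HP difference of 0.15 z.

## Numerical and degenerate-input conventions

* RT filter: keep `300 ≤ rt ≤ 4,000` ms — both printed cutoffs retained.
* Artifact threshold: strictly greater than 10 pixels; a 10-pixel step is
  clean. The 3-SD rule is likewise strict (a bin at exactly 3.0 is kept).
* Zero-variance subjects (RT or pupil) are errors, not silent NaNs.
* Singular mixed-model fits (variance component at zero) are returned
  with lme4's message, never silently dropped; step-down then removes
  them via the LRT.
* Bins overlapping remaining invalid samples are invalid, not partially
  averaged; interval means skip missing bins and return NA only when a
  window is entirely missing.
* Determinism: every stochastic routine takes a seed; the pipeline
  derives all its seeds from the master seed, and identical
  configuration + seed reproduces the report byte for byte.

## Problem sizes used by the test suite

The replicated studies in the test suite use sizes chosen as the smallest
that make the statistical claims sharp: null calibration of the type-III
F at 500 replicates of 8 subjects × 24 trials, permutation-correlation
calibration at 2,000 replicate datasets of n = 80 with 999 permutations
each (the attainable level is then exactly 0.05), and effect recovery at
50 replicates of 40 subjects with the full 1 kHz pupil chain. The
acceptance script analyzes one 94-subject synthetic study end to end.

## Known limitations

* The agent is a stand-in: it reproduces the observable statistics the
  classifier consumes, not human learning dynamics; model-based inference
  on real choices is out of scope.
* No deconvolution of overlapping pupil responses; carryover is
  represented, not removed.
* No gaze-position modeling; stimulus position is simulated and ignored,
  as the task counterbalances it.
* The ASC-dialect reader covers samples and messages only (no
  saccade/fixation events, no binocular records).
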