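---
title: "Models and methods behind accumtowers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind accumtowers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accumtowers)
```

## The task and its data

`accumtowers` simulates and analyzes a pulse-based evidence-accumulation
task for head-fixed mice navigating a virtual T-maze. As the animal runs
down a 330-cm stem, brief visual cues (towers) appear on the left and
right walls of the first 200 cm (the cue region); the final 100 cm (the
delay region) is cue-free, and reward is delivered in the arm on the side
that carried more towers. The atom of every analysis is the per-trial
record: tower positions per side, rewarded side, choice, outcome, and
quality flags, stored as a tibble with list-columns and serialized as
JSON-Lines (`read_session_log()` / `write_session_log()`). Within-trial
trajectories (time, position, view angle) are plain CSV.

The package has two halves that validate each other: a *generator* (task
protocol plus synthetic agents) that produces data with known ground
truth, and an *analysis stack* (psychometrics, evidence weighting, choice
models, an accumulator model, signal-detection counting models, and
cross-validated model comparison) whose estimators are tested by
parameter recovery against that ground truth.

## Stimulus generation

Tower counts are Poisson with means 7.7 on the rewarded side and 2.3 on
the minority side *per cue period*: the stated overall density of
5 towers/m over the 2-m cue region forces this reading, and it matches
the reported median of 10 total towers. Counts are capped at the packing
limit of the cue region — with towers allowed in [10, 200] cm and a
12-cm within-side refractory distance, at most
`1 + floor(190 / 12) = 16` towers fit on one side — and the whole trial
is redrawn until the rewarded side holds a strict majority, since reward
follows the majority side by construction and ties are impossible in the
task. Conditioning on a strict majority shifts the realized means
slightly (to about 7.93 and 2.18; the unconditioned draw stage is
exposed separately via `draw_tower_counts(conditioned = FALSE)`).

Positions are uniform given the count, subject to the refractory
spacing, sampled *exactly* by the gap transform: the minimum gaps are
removed from the span, order statistics of uniforms are drawn on what
remains, and the gaps are re-inserted. This is distributionally identical
to rejection sampling (verified by two-sample tests) but always
terminates. The refractory period applies within a side only; the two
sides are independent, which is why up to 16 towers can appear on one
side but more than 16 in total.

## Protocol simulation

Three pieces of rig logic are reproduced because they shape the
statistics of real session logs:

* **Debiasing.** The probability of drawing a right-rewarded trial is
  `p_R = e_R / (e_R + e_L)`, where `e_R` and `e_L` are half-Gaussian
  weighted (sd 20 trials) error rates over the last 40 trials of each
  side, with `sqrt(e)` capped into [0.15, 0.85]. A pseudo-random
  prescription (comparing the realized right fraction under a sd-60
  half-Gaussian window with `p_R`) then steers the sequence toward the
  target faster than independent draws would. Cold start uses
  `p_R = 0.5`, and the kernels are normalized over available history.
* **Shaping.** Sessions begin in a visually-guided warm-up maze and
  advance once at least 10 warm-up trials reach 85% correct with at most
  a 10% side bias and 75% good-quality trials; a 40-trial running window
  below 55% correct in the main maze triggers a 10-trial single-sided
  easy block. Warm-up (maze level 0) and easy-block (level 10) trials
  are stored but excluded from analysis by default.
* **View-angle controller.** The exponential gain
  `dtheta/dt = sign(Theta) min(exp(1.4 |Theta|^1.2) - 1, pi)` maps
  treadmill displacement angles to rotation rates, damping small angles.
  The rig's raw sign convention makes rightward displacements negative;
  logs store the package-wide convention (positive = rightward), chosen
  once so that the choice-decoder definition reads as an accuracy.

## Synthetic agents and trajectories

Agents map a trial (and optionally the previous trial) to a right-choice
probability: a constant-p agent, hypergeometric k-random-tower choosers,
first/last-tower heuristics, the history-modulated logistic model below,
and a Monte-Carlo accumulator agent that forward-simulates the
stochastic accumulator with 0.5-cm Euler steps. The accumulator agent is
deliberately algorithmically independent of the likelihood propagation so
the two can cross-validate each other; its sampled choice is a single
fresh path, which is an exact Bernoulli draw from the model's p_R.

Trajectories have no inferential model in the package (none exists for
the task); the generator is a labeled stand-in that reproduces the
qualitative structure of real running: a logistic-in-position mean view
angle toward the chosen side whose midpoint shifts earlier with
|#R − #L|, Ornstein–Uhlenbeck view-angle noise around it, per-session
and per-trial speed variation (defaults 61 ± 8 cm/s across sessions,
± 5 within), and a zero view angle in the 30-cm start buffer. Trial-level
noise dominates the choice-mean difference by design (the spread ratio
exceeds 5), as in the recorded behavior. Passing kinematics tests on
these trajectories shows the estimators work, not that real mice move
this way.

## The analysis stack

**Psychometrics.** Choices are binned by the tower difference
Δ = #R − #L in groups of three (anchored so {−1, 0, 1} is the central
bin) with trial-weighted abscissas, and fit with the four-parameter
sigmoid `p_R = b + a / (1 + exp(-(Δ - Δ0)/λ))` by weighted nonlinear
least squares (per-bin binomial weights; bounds b in [0, 0.5], a in
[0, 1] keep the asymptotes interpretable as lapses). The slope at the
midpoint is `a/4λ` and the lapse rate is the error percentage on trials
with |Δ| ≥ 10, with Jeffreys 1-σ (Beta quantile) intervals. The sigmoid is fit
to binned proportions by default; a single-trial maximum-likelihood
route would be a straightforward variant. Degenerate, step-like data
return a flagged fit rather than an error.

**Top-block surrogate test.** Selecting each animal's best blocks
trivially improves performance measures; the test redraws choices from
the fitted static curve at the experienced Δs (200 surrogates),
re-selects the top 10% of blocks (ties broken by block length then
index; mice dropped below 300 remaining trials), and asks whether the
observed slope/lapse improvements exceed the surrogate distribution.
Under a genuinely static curve the p-values are calibrated; planted
low-lapse blocks are detected through the lapse, not the slope, because
easy trials contribute little to overall block performance.

**Performance factors.** Percent correct per 3-way bin (|Δ| in twos,
total towers in twos, effective cue or delay duration in 10-cm bins,
where effective cue duration is last-minus-first tower position and
effective delay is 300 minus the last position) is mouse-mean-subtracted,
averaged across mice, and fit with a 3-parameter linear regression whose
t statistics use n − p − 1 degrees of freedom.

**Spatial evidence weighting.** Choice is regressed on the net evidence
in five equal segments of [10, 200] cm (half-open bins, the last closed
so a tower at exactly 200 cm counts) by unregularized logistic maximum
likelihood; coefficient errors come from 200 trial-resampling bootstrap
refits, and a tiny-ridge refit is used (and flagged) only on complete
separation. The weight decay ratio mean(β4, β5)/mean(β1, β2) quantifies
primacy (< 1) versus recency (> 1); its null distribution shuffles the
five design-matrix entries within each trial (200 refits) — the
within-trial column permutation is chosen over tower-label shuffling
because the two produce equivalent nulls for balanced designs and the
former preserves each trial's evidence multiset exactly.

**History models.** The nested logistic family
`p_R = l_L + (1 - l_L - l_R) logistic(p0 + (1 + βe·e)(β0 + βΔ'Δ))`
reduces to the constant `f_R` model when all free parameters vanish
(`p0 = qlogis(f_R)`). Lapses depend on the previous trial through
`l_R = (1 - cos(b0R + βh'h))/2`, `l_L = (1 - cos(b0L - βh'h))/2` with
`h = (prev choice, prev outcome, interaction)` coded ±1, keeping both in
[0, 0.5]. Two numerical choices matter here. First, the argument bound
is enforced by a smooth odd saturation `(π/2) tanh(2x/π)` rather than a
hard clamp: the clamp's flat regions leave a quasi-Newton optimizer
without gradients and trap fits in a no-lapse saddle (the cosine
transform is stationary in all five lapse parameters at zero, so
displaced deterministic starts are always included). Second, the even
cosine makes jointly negating (b0R, b0L, βh) an exact symmetry; fits are
canonicalized to a nonnegative baseline sum. Fitting maximizes the
likelihood by box-bounded quasi-Newton with analytic gradients; an L1
penalty on all parameters is available (smoothed absolute value) with
weight 0 by default, and the shrinkage path of the history weights is
monotone in the penalty.

The evidence vector is either the five spatial bins or the *cue-order*
design: towers pooled across sides are ranked by position (cross-side
ties right-before-left), ranks are downsampled by three, and coordinate
j is #R − #L among ranks 3(j−1)+1…3j. The dimensionality is the largest
j for which at least 50 trials carry a complete j-th triplet; shorter
trials contribute zeros, and each vector is divided by the square root
of the mean |Δ| among trials with the same total count (per-count
normalization, with a dataset-mean fallback for unseen counts at
prediction time).

**Alternative strategies.** The k-random-tower model is the
hypergeometric probability that a majority of k towers drawn without
replacement is on the right (even-k ties count half; k is clipped to the
trial total; zero-tower trials get 0.5), mixed with side lapses measured
on single-sided trials. First/last-tower models use the side of the
extreme tower. At a fixed total count the one-random-tower model
predicts a right-choice probability exactly linear in #R, which the
linearity test exploits: the statistic is the count-weighted squared
deviation of the observed per-Δ choice fractions from the line, with a
null built by simulating choices from the line at the observed trial
counts. This parametric null was chosen over permutation schemes
because its calibration (uniform null p-values under the line model) is
directly checkable, and the tests check it.

**Accumulator (drift-diffusion) model.** The latent variable evolves
over maze position y in meters: leak/instability λ (memory constant
1/λ), diffusion variance σ²a per meter, per-pulse sensory noise
η ~ N(1, σ²s) multiplying the adapted pulse magnitude C, initial value
a0 ~ N(0, σ²i), sticky bounds ±B, and at the stem end a right choice if
a exceeds the bias (absorbed mass decides by bound sign), mixed with a
lapse. Adaptation is shared across streams: each pulse is delivered at
the running magnitude C (starting at 1), after which C is multiplied by
Φ and recovers toward 1 with constant τΦ. The noise convention keeps
the three sources separate — a0 from N(0, σ²i), η from N(1, σ²s),
diffusion σ²a per unit y — and pulse variance scales multiplicatively
as σ²s·C² (noise rides on the adapted magnitude). Fit bounds: −5 < λ < 5,
0 < σ²a, σ²s < 200, 0 < σ²i < 30, 5 < B < 25, 0 < Φ < 1.2,
0.001 < τΦ < 2, −5 < bias < 5, 0 ≤ lapse ≤ 1.

Trial likelihoods are exact distribution propagations on a grid spanning
[−B, B] with absorbing bound bins. Between events the linear SDE is
advanced with its closed-form map (decay e^{λΔy}, exact accumulated
variance), subdivided so absorption is checked at least every `dy_max`;
pulses convolve with a Gaussian centered at ±C with sd √σ²s·C. Deposits
use two-point interpolation (mass- and mean-conserving), kernels are
discretized at the subpixel-centered offsets, and thresholding uses cell
fractions, so probability mass is conserved to 10⁻⁸ and the noise-free
mean matches the closed-form leak solution to 10⁻⁶. Per-trial
probabilities default to a 281-point grid with 1-cm checks (halving the
step moves p_R by < 10⁻⁴); fitting uses a coarser, faster configuration
(61–101 points, pulse-position checks, drift applied by interpolation
with one shared diffusion kernel per interval) that agrees with the fine
propagation to ~2×10⁻³ and is maximized by quasi-Newton iterations on
transformed parameters (log variances, scaled-logit bounded parameters)
with central-difference gradients, which are accurate at these scales.
The likelihood can be genuinely multimodal in the leak for
weakly informative data; deterministic leak-displaced starts are
included, and recovery tests use leaks the data can identify.

**Signal-detection counting model.** Each side's count is perceived as a
Gaussian centered on the true count; the probability of choosing the
larger side is `Φ((L−S)/√(σ²L+σ²S))`, the closed form of the defining
integral (verified against quadrature to 10⁻⁸). The full model fits one
σ per count 0…15 (trials with more than 15 towers on a side are dropped
whole; intended for aggregate data), and the two-parameter laws fit
σ(n) = β0 + β1·n (scalar variability) or σ²(n) = β0 + β1·n (linear
variance) with β0 ≥ 0. All σ are floored at 10⁻³ towers — σ0 multiplies
a count of zero and is otherwise unconstrained, so the floor prevents
degenerate certainty; near-noiseless data drive fits to the floor and
are flagged. The bootstrap comparison refits both laws on 1,000 trial
resamples and reports the proportion won by each, scored by model
information against a shared constant-accuracy reference.

**Model comparison.** All choice models are scored by 70 runs of 3-fold
cross-validation with fold assignments drawn once and shared across
models; `f_R` for the reference model is computed on the training fold
to avoid leakage. The model information index is
`MI = (lnL − lnL0)/(n ln 2)` bits/trial, summarized by the median across
all 210 fold evaluations (the run-level-mean alternative is a trivial
variation on the returned per-fold table); pairwise significance is the
proportion of fold evaluations in which one model underperforms the
other, ties counted half, and a model failure on a fold removes that
fold for every model so comparisons stay paired. Trials are assigned to
folds independently because every model treats trials as conditionally
independent given explicitly precomputed history regressors. The FDR
rule is implemented literally as printed — flag the i-th ranked p-value
iff `P(i) ≤ αi/n` — with the conventional step-up sweep available
behind `stepup = TRUE`.

**Kinematics.** The view angle at position Y is the angle at the first
sample with y ≥ Y (no interpolation, robust to backtracking). The choice
decoder finds, per position, the boundary equalizing the two
misclassification fractions by bisection on the empirical CDFs — a
rank-based construction invariant to monotone transforms of the angle —
and reports the percent of right-choice trials above it. Tower-triggered
analysis subtracts each trial from its choice-conditioned mean
trajectory and averages deviations over 80 cm after each tower,
reporting also the ratio of across-trial spread to the choice-mean
difference. Stem speed is summed x-y path length over 0 < y < 300 cm
divided by traversal time (path length rather than net displacement, so
backtracking is not understated), with within-/across-session standard
deviations; evidence-conditioned mean view angles align each mouse to
the aggregate before averaging.

## Trial selection

Block-wise inclusion follows the task's standard criteria: whole blocks
(maximal runs of same-maze-level trials within a session) below 60%
correct are dropped; trials exceeding 110% of nominal travel, timed-out
or aborted trials are removed; mice need 1,000 surviving trials.
History analyses additionally drop the first k trials of each block and
whole opto-containing sessions, keeping consecutive-trial structure
intact (the alternation-bias functions refuse non-consecutive input).
An exclusion ledger is returned so counts always partition the input,
and an empty result is an error, never a silent empty table. The
sliding-Gaussian low-performance-bout filter defaults to a 10-trial sd
and a 0.55 threshold; both are exposed as arguments.

## Problem sizes and what the tests show

The test suite regenerates all of its data (nothing is shipped):
stimulus statistics at 20,000 trials, dual-route oracles (propagation vs
100,000-path Monte Carlo on a 20-point grid; hypergeometric vs
exhaustive enumeration for all totals ≤ 10; closed form vs quadrature),
parameter recovery at 20,000 trials for the logistic models, 50,000 for
the counting-model laws and 10,000 for the accumulator, and
200-experiment null calibrations for the shuffle and permutation tests.
Unit tests use smaller sizes of the same constructions. Passing these
shows the estimators are correct and calibrated on data satisfying the
generators' assumptions; real behavior (satiety drift, motor events,
non-stationary strategies) can violate them in ways synthetic data do
not probe.
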