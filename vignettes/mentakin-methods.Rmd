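---
title: "Models and methods behind mentakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mentakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mentakin implements the analysis chain of a double-blind, placebo-controlled
crossover experiment on dopaminergic modulation of mentalising: kinematic
similarity metrics from two-triangle animation trajectories, the
animations-task scoring scheme, drug-minus-placebo change scores, and a
suite of Bayesian hierarchical models with posterior-probability reporting
and leave-one-out model comparison. Because the real cohort is external to
the package, everything is exercised end to end on synthetic cohorts whose
true effects are known. This vignette records the models, the generative
assumptions, and the numerical choices, so that a reader can judge exactly
what passing tests do and do not demonstrate.

## The measurement model

Each of the four rating scales (one per target word) runs from 1 ("not at
all") to 10 ("very"). The **accuracy score** of a trial is the rating of the
target word minus the mean rating of the three non-target words; with 1–10
scales it lies in [−9, 9]. Positive values mean the target was preferred,
values near zero mean confusion between scales. The **binary transform**
calls a trial correct when the target received the *strictly* highest
rating; a tie with any non-target counts as incorrect. Ties are not broken
at random: the strict reading is conservative and deterministic (the
rating-scale resolution makes exact ties rare in practice). **Percentage
accuracy** is the proportion correct over a word's 8 trials in one session,
so it lives on the lattice 0, 1/8, …, 1, and the **animations accuracy
change score** (haloperidol minus placebo percentage accuracy) lies in
[−1, 1]. Emotion-recognition accuracy reuses the target-minus-mean-non-target
construction over the three emotion scales; this is an assumption, since the
original ER scoring lives in earlier work on that task.

**Jerk** is the third time-derivative of position. A trajectory's mean jerk
is the average, over interior frames and both agents, of the Euclidean norm
of the third-order central difference of the positional series,

$$ f'''(t_i) \approx \frac{f_{i+2} - 2f_{i+1} + 2f_{i-1} - f_{i-2}}{2h^3}, $$

which is exact on cubic polynomials (the test suite checks this to 1e-6
relative error, and checks sinusoidal trajectories against quadrature
oracles to 0.5%). Mean speed uses the first-order central difference. No
smoothing is applied by default: the 133 Hz positional series is the stated
raw input, and any pre-filter would change the jerk statistic being studied.
Boundary frames where a stencil is undefined are dropped ("non-null"
derivative values only); zero-motion interior frames are kept, since
excluding them would redefine the statistic. Timestamps may jitter by up to
1% of the nominal step (divided differences then use the nominal step);
larger non-uniformity raises an error rather than silently degrading the
derivative estimates.

The **jerk difference** for a viewed animation is |self − stimulus| where
"self" is the observer's own mean jerk when animating the same word and
"stimulus" is the animation's mean jerk — an observer–animator movement
similarity index (lower = more similar). The *same-session* variant takes
the self jerk from the trial's session; the *placebo-based* variant always
takes it from the placebo session, so the two coincide on placebo trials.
Self-produced jerk is pooled over the two triangles the participant
animates, matching the two-agent average used for stimuli (the alternative,
per-finger jerk, is not separately recoverable from the pooled statistic).

## The model suite

All models are fitted by MCMC with zero-centred normal priors on the
intercept and coefficients and half-Cauchy priors on every standard
deviation. Continuous predictors are standardised (z-scored, n−1
denominator) over the full analysis table before fitting, so slopes are
per-SD effects and "per 2 SD" statements multiply a slope by 2. Reference
levels are fixed throughout: drug → PLA, mental state → non-mental. The
registry (see `build_model()`) spans:

* **1.1–1.4** — accuracy on drug (plus mental state, drug day, or arousal),
  with uncorrelated random subject intercepts and drug slopes
  (`(1 + drug || subject)`) and random animation intercepts. Arousal
  (tiredness, 1–10) enters as an ordered factor with orthogonal polynomial
  contrasts capped at degree 7; the cap keeps the reported trend structure
  even when all 10 levels are observed.
* **2.1–2.3, 3.1–3.2** — the jerk-difference models: the three-way
  drug × mental-state × jerk-difference structure, placebo/haloperidol
  subsets, and the placebo-based jerk difference variants. One reported
  formula contains the malformed random term "(1 + subject ID)"; it is read
  as a random subject intercept.
* **4.1–4.2** — accuracy *change* on ER change (and WM change), a Student-t
  response truncated to [−1, 1] because change scores are bounded
  proportions. The t degrees of freedom get a gamma(2, 0.1) prior — a
  standard weakly informative choice; the source analyses do not print one.
* **5, 6.1–6.3** — accuracy with the response modelled as a **mixture of two
  Gaussians**, for cohorts whose accuracy distribution is bimodal (a low
  "confused" and a high "discriminating" component).
* **7.1–7.2** — walking speed on drug × baseline working memory with random
  subject intercepts.

Prior scales are a design choice (the source analyses state the families
but not the scales): normal(0, 2.5) for coefficients on the standardised
scale, normal(0, 10) for the intercept (the accuracy response is not
centred), half-Cauchy(0, 2.5) for SDs.

### Sampling, diagnostics, reproducibility

The engine is JAGS via rjags. Defaults follow the declared protocol: 4
chains, 5000 iterations each with 1000 warmup. One master seed fans out
per-chain RNG seeds deterministically, so identical seed + data reproduce
identical draws. Convergence is gated on split-Rhat ≤ 1.01 over all
monitored quantities; a fit failing the gate is flagged (and warns), never
silently accepted. Divergent transitions are a Hamiltonian-sampler
diagnostic; JAGS' conditional samplers have none, so the `divergences`
field is structurally 0 and Rhat carries the diagnostic burden.

Posterior summaries report the mean (Eμ), the *equal-tailed* 95% credible
interval (2.5/97.5 percentiles, matching the standard reporting convention
of this model family rather than HPD intervals), and the sign probabilities
P(Eμ<0) and P(Eμ>0) as empirical tail fractions of the draws (ties at
exactly 0 are split, so the two always sum to 1). Implied slopes in
non-reference conditions — e.g. the jerk-difference slope for mental-state
animations — are summarised from the draw-wise sum of the base and contrast
coefficients (`derived_coefficient()`), not from the sum of the reported
means alone, though the two coincide for the posterior mean.

### Mixture identifiability

The two-component Gaussian mixture replaces the global intercept with
component intercepts constrained to ascending order (sorted inside the
sampler), which removes label switching. The summary reports component
means at the average linear predictor, component SDs, the mixing proportion
of the lower component, and the empirical split point — the accuracy value
between the component means where posterior responsibility flips. A fit is
flagged degenerate when a component's weight concentrates at a boundary
(< 0.05 or > 0.95) or when the component means sit within 2 SD of each
other (the fitted mixture is then itself unimodal and labels are
arbitrary) — the expected outcome when the generator's mixture weight is 0.

### PSIS-LOO

Model comparison uses Pareto-smoothed importance-sampling leave-one-out
cross-validation, implemented in-package: per observation, the importance
ratios 1/p(y_i | θ_s) have their largest min(S/5, 3√S) values replaced by
expected order statistics of a generalised Pareto distribution fitted to
the tail (Zhang–Stephens profile-posterior estimator with the usual weak
prior shrinkage on the shape). Observations with shape k̂ > 0.7 are counted
and reported (`n_high_k`); at the desk scales used here an exact refit is a
viable fallback, and the test suite validates the smoothed estimate against
brute-force refitting on a conjugate model. `elpd_diff` is reported against
the best model with the standard error of the pointwise differences; model
weights are pseudo-BMA (normalised exp(elpd)) — the simplest published
weighting, chosen over stacking for transparency.

## The synthetic cohort generator

The generator is the package's test bed: it emulates all five data streams
of the crossover under known ground truth (`generator_params()`), with
default effect sizes set to the reported headline estimates of this design —
drug effect −0.66 and mental-state effect −2.50 accuracy points,
jerk-difference slopes −0.11 (non-mental) and −0.54 (additional mental
contrast) per SD of jerk difference. Default variance components (subject
intercept SD 1.0, subject drug-slope SD 0.5, animation SD 0.5, residual SD
2.0 accuracy points) are plausible magnitudes for rating-scale data of this
kind; they are design choices, as is the default cohort size of 33
subjects. Counterbalancing is exact: with even n, half the subjects are
HAL-first; each session holds 32 animation trials (8 per word), 48 emotion
trials, working-memory trials at set sizes 5–9, and a 120-s walk.

Trial ratings are built *backwards from the accuracy statistic*: a latent
accuracy is drawn from the linear predictor (grand mean + drug + mental
state + jerk-difference terms + random effects + residual, optionally
displaced by a second mixture component), clipped to [−9, 9], and mapped to
target = 5.5 + a/2 and non-targets = 5.5 − a/2 plus mean-centred jitter
(SD 0.3). Before the final clip to [1, 10] the trial's accuracy score
equals the latent value exactly, which makes the scoring module testable
against ground truth.

Trajectories are a stand-in, not a reconstruction — no generative
description of the real finger-drawn triangle motion exists. Each agent
moves at constant speed along a smoothly turning heading (three random
sinusoidal heading-rate components), steered toward the canvas centre with
a quartic wall repulsion; the wiggle amplitude is calibrated numerically
(two secant steps) toward the requested mean jerk. Constant step length
makes realised mean speed track its target to well within the contractual
±10%. Word-specific speed bands (seducing slowest, fighting fastest, in
canvas units/s on a 1024 × 768 canvas) make the speed-stratified selection
of 8 stimuli per word meaningful. Because synthesising and differentiating
4655-frame paths for every stimulus and self-animation is unnecessary for
model validation, the generator's default `trajectory_mode = "summary"`
draws kinematic summaries from the same word-banded distributions directly;
`"full"` mode generates real paths and summarises them with the kinematics
module, and the pipeline and trajectory tests use it.

Auxiliary streams: emotion stimuli carry mean speeds ordered sad < happy <
angry (1.0/1.5/2.2 m/s, SD 0.08); a subject's ER drug effect is
`er_coupling_slope` times their animation drug random slope plus noise,
which is what lets the ER-change models find (or, with the slope at 0, not
find) a coupling. Working-memory accuracy follows the subject's baseline
span with a set-size penalty; its drug effect is noise-only by default,
mirroring the null WM finding this design anticipates. Walking speed gets a
drug effect moderated by standardised baseline WM (default −0.05 m/s drug
effect, +0.05 interaction: low-WM subjects slow more). Under haloperidol a
subject's *produced* jerk shifts by +0.15 on the log scale — without this
the same-session and placebo-based jerk differences would be
indistinguishable and the placebo-jerk models would have nothing to detect.
Noise models for all auxiliary streams are Gaussian on the relevant scale,
truncated to valid ranges.

What the generator does **not** emulate: attrition (every synthetic subject
completes both days), response-time structure, sequence/order effects
within a session, realistic human motor noise (tremor, drift), or
rating-scale usage idiosyncrasies (anchoring, integer preference). Passing
tests therefore show that the pipeline recovers known effects from data
*of this structure*, not that the structure is a faithful model of human
raters.

## Validation design and problem sizes

The test suite validates each module against independent oracles:
finite-difference kinematics against analytic derivatives and quadrature;
scoring against hand-computed examples and lattice/bound properties; the
PSIS smoother against brute-force leave-one-out refits; bimodality control
via an external Gaussian-mixture BIC check. Model validation uses
simulation-based checks at deliberately modest scale, chosen to keep the
full suite in the minutes range: single-fit recovery for models 1.1, 1.2,
2.1, 4.2 and the mixture model on cohorts of 30 subjects generated from
each model's own structure (every fixed effect within 3 posterior SDs of
truth); 25 replicate fits of model 1.2 on 12-subject cohorts for sign
recovery (≥ 23/25 negative drug-effect posterior means at the default
effect magnitude) and credible-interval coverage (≥ 20/25); and 10
replicate LOO comparisons confirming a pure-noise predictor never wins
beyond its standard error more than twice. Replicate fits use 2 chains of
700–1700 iterations — enough for stable posterior means at these data
sizes, while full analyses should keep the 4 × 5000 default.

## Known limitations

* Random effects are uncorrelated by construction (`||`); correlated
  intercept–slope structures are not implemented because no model in the
  registry needs them.
* The truncated-t and mixture families are fitted with generic conditional
  samplers; very small cohorts (< 8 subjects) can mix slowly, and the
  split-Rhat gate will flag this rather than fail loudly.
* PSIS-LOO uses the conditional (random-effects-given) likelihood, so
  comparisons answer "predict a new trial of a known subject", not "predict
  a new subject".
* The trajectory generator targets mean speed tightly but mean jerk only
  approximately; jerk-sensitive analyses on synthetic trajectories should
  use the realised summaries computed by the kinematics module (as the
  generator itself does in `"full"` mode), never the requested targets.
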