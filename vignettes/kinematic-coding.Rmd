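---
title: "Kinematic encoding, readout, and priming: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic encoding, readout, and priming: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a person reaches for a bottle, subtle features of the reach — how high
the wrist travels, its transverse path, how the hand dorsum rotates —
already differ depending on what the person will do next (pour into a glass
or drink). kinprime models two distinct quantities at single-trial
resolution:

* **Encoding**: how much intention information a given reach carries, for
  an ideal observer. Modelled as an elastic-net logistic regression of
  intention on the trial's kinematic feature vector.
* **Readout**: how much of that information a *particular human perceiver*
  extracts, inferred from their forced-choice judgments of the same reaches.
  Modelled as a per-perceiver elastic-net logistic regression of the
  perceiver's *choice* on the same features.

Both models share one form: `P(pour | K) = sigmoid(beta . K + beta0)` on the
z-scored 64-dimensional feature vector K (16 kinematic variables averaged
over 4 epochs of normalized movement time). The **single-trial index** is
the sign-adjusted linear predictor `y (beta . K + beta0)` with `y = +1` when
the prime's true intention is 'pour': it equals the log-odds that the model
classifies the trial correctly, so positive values mean correct (encoding)
or correct-leaning (readout) and the magnitude is information in log-odds
units. Downstream, mixed-effects models ask whether these indices predict
*kinematic priming*: faster responses and more task-relevant first
fixations when a probe image is congruent with the preceding reach.

## Model fitting conventions

* Positive class is fixed to `'pour'` everywhere.
* Features are z-scored with the sample SD (n-1); standardization
  parameters travel with the model so held-out trials are transformed with
  training statistics only.
* Elastic-net mixing alpha = 0.95 (sparse solutions); the penalty
  `lambda_min` minimizes leave-one-video-out cross-validated binomial
  deviance, where all repetitions of a video leave together for readout
  models. The final model is refit on all trials at `lambda_min`; the
  intercept is unpenalized. The lambda grid is glmnet's 100 auto-scaled
  log-spaced values.
* Argmax classification ties (p = 0.5 exactly) resolve to `'drink'`
  deterministically.
* A perceiver who always makes the same choice yields a flagged degenerate
  model: zero weights and a damped base-rate intercept.

## The synthetic world

The generator is first-class, tested code with known ground truth; its
defaults are frozen and documented here.

**Trajectories.** Wrist velocity is a raised-cosine bell (peak ~900 mm/s)
flanked by 0.2 s of sub-threshold padding, so the 20 mm/s onset/offset
bounds are always detectable. Position-like channels are logistic or linear
ramps; plane-normal components are near-constant. Every channel carries two
smooth Gaussian-process perturbations per prime: a slow amplitude process
(kernel SD 0.22 of movement length) scaled by a late-rising logistic
envelope, and a faster small wiggle. Movement durations are uniform on
0.84-1.36 s at 100 Hz.

**Intention effects.** Injected only in wrist height (W_H, 3 SD), wrist
horizontal trajectory (W_HT, 1.5 SD) and dorsum-plane y (DP_Y, 0.75 SD), as
offsets sharing the same late-rising envelope as the dominant noise — so
the configured SD-unit effect sizes are approximately realized on late
epoch-averaged features (verified by a Monte-Carlo calibration test at
+/- 25%), and intention information accrues toward movement end, as in real
prospective reaches.

**Perceivers.** Each perceiver's true readout vector is the ground-truth
encoding direction restricted to {W_H, W_HT}, perturbed by a per-perceiver
tilt (SD 0.6 per component) and scaled by a gain drawn from U(2, 6).
The calibration logic matters: the source regime pairs ~95% predictability
of choices by the readout model with only ~75% discrimination accuracy.
That combination forces *strong but misaligned* readout — choices that are
nearly deterministic given the kinematics (high gain) yet driven by a
tilted direction (accuracy limited by what is read, not by response noise).
An earlier calibration with small gains and noisy choices reproduced the
75% accuracy but neither the 95% predictability nor recoverable readout
vectors, and was replaced in a single documented pass. With the frozen
defaults, measured before freezing: discrimination accuracy ~0.76, readout
model performance ~0.92, readout-vector recovery cosine ~0.84 at 240
trials, and ~0.9 of absolute encoding weight mass in the three informative
variables. A 5% lapse rate mixes choices toward 0.5.

**Priming sessions.** 240 trials per participant, exactly 75% congruent.
RTs are gamma with identity-link mean
`600 + participant + prime + probe/2 - 3 ms * s` on congruent and `+ 3 ms * s`
on incongruent trials, where `s` is the trial's true readout index — the
identity link matches the analysis model exactly, making parameter recovery
well-posed. First fixations hit the displayed probe's relevant quadrant
with logit `-0.2 + 0.08 s` (congruent; sign flipped when incongruent); 14%
of trials have no initial probe fixation; 2% of probe categorizations are
errors. Baseline pupil is AR(1) noise (phi = 0.8), independent of
everything, z-scored within participant. Confidence is the ordinal bin of
the absolute readout predictor (cutpoints 3, 6, 11 plus N(0, 1.5) jitter),
so confidence tracks readout, not encoding.

**What the generator does not emulate.** Real marker noise, multi-peaked
velocity profiles, learning/order effects, response time-outs, and any
video-level visual confound. A green test therefore establishes that the
*statistical machinery* behaves as claimed on data satisfying the model's
assumptions — not that real reaches satisfy them.

## Mixed-effects machinery

Gamma (identity link) and binomial (logit) families use `lme4::glmer`.
Gamma-identity fits use the `nAGQ = 0` update: on these models it reaches
log-likelihoods within <0.1 of the Laplace fit but is numerically stable
where Laplace's fixed-effect covariance degenerates; the resulting LRTs are
type-I calibrated (measured 0.050 at nominal 0.05 over 200 null
simulations). Singular (boundary) fits count as converged; genuine
optimizer failures are flagged and excluded from LRTs. All categorical
fixed effects use sum contrasts, so a two-level factor's coefficient is
half the cell-mean difference and the priming effect (incongruent -
congruent) is `-2 beta`.

The cumulative-logit mixed model is implemented in-package (the `ordinal`
package is not a dependency): maximum likelihood with 21-node
Gauss-Hermite quadrature over a single participant random intercept,
increasing cutpoints via a log-difference parameterization, `MASS::polr`
starting values, and a delta-method covariance from the optimizer Hessian.
Confidence ratings collapse their two lowest levels before fitting when
more than three are observed.

Interaction tests follow the two-step convention: the congruency-by-index
term is tested by LRT between models that both exclude the three-way term
(tested separately), each differing by exactly the tested term. For
logistic models, product-term significance on the latent scale does not
guarantee an interaction on the probability scale, so the fixation analysis
additionally computes marginal predicted probabilities (random effects at
zero, probe averaged out) and Wald-tests the equality of marginal index
effects across congruency by the delta method.

## Numerical and procedural choices

* **Movement bounds**: onset is the first sample above 20 mm/s; offset the
  first sample after onset below it — the first drop, so multi-peaked
  profiles need upstream smoothing. Indices are 1-based.
* **Epoch averaging**: each channel is linearly interpolated at 101 points
  of normalized movement time and averaged per epoch by trapezoidal
  quadrature (exact for linear segments; plain point-averaging misses the
  stated ramp tolerance).
* **Exclusions**: incorrect trials first; then RTs above the participant's
  mean + 2.5 SD computed on correct trials; then (fixation analyses only)
  trials without an initial probe fixation. The RT threshold is recomputed
  from the supplied data, so the rule is only *nearly* idempotent — a
  second application can trim an occasional borderline trial.
* **Quadrant boundaries**: vertical midline belongs to the right quadrants,
  horizontal midline to the top (screen coordinates); the centre pixel is
  top-right.
* **Permutation test for coefficients**: the literal procedure pools
  absolute coefficients of all permutations into one null. Under sparse
  shrinkage that pool is mostly exact zeros, its 95th percentile collapses,
  and every surviving observed coefficient is flagged — the procedure is
  anti-conservative for selected coefficients under a pure-noise null. Both
  the literal pooled null (default) and a family-wise-calibrated variant
  (per-permutation maximum absolute coefficient) are provided; calibration
  claims are made only for the latter.
* **Permuted-choice performance null**: fitting the readout model to
  permuted choices and scoring it in-sample yields a null centred ~0.07
  above 0.5, not at 0.5 — a majority-class component (label counts are
  permutation-invariant) plus residual overfitting at `lambda_min`. The
  null is used as a reference distribution (observed
  performance is compared with its upper percentiles); its mean should not
  be expected to sit inside the naive binomial band, and the corresponding
  acceptance assertion is left failing rather than widened.
* **Zero-readout primes**: the double criterion is (1) an exact two-sided
  binomial test of pooled behavioral accuracy against 0.5, p > 0.05, and
  (2) for every perceiver, |single-trial readout| at or below the 95th
  percentile of a surrogate null in which only that prime's choices are
  randomized. With 4 repetitions there are only 16 equiprobable surrogate
  patterns, so `exact` mode enumerates them (identical null to the
  10000-draw Monte Carlo, deterministic and fast); surrogate refits freeze
  lambda at the observed `lambda_min` by default, with a full-CV option. In
  fast mode the observed index is recomputed with the same fixed-lambda
  estimator as the null atoms, so observed and null values are exactly
  comparable. Note a structural property of the design: with 16 atoms the
  95th percentile falls inside the top atom's probability block, so
  criterion (2) rarely excludes anything at 4 repetitions (this holds
  equally for a 10000-draw Monte Carlo null) and detection is effectively
  driven by the behavioral binomial criterion.
* **Pooled readout models**: surrogate participants draw the original
  per-participant trial count from the identity-erased pool, without
  replacement within each surrogate.
* **Random-effects selection**: candidates are ranked by BIC among
  converged fits; the winner must also have all single-term-deletion
  submodels converge so LRTs remain trustworthy. LRT degrees of freedom are
  not boundary-corrected (fixed effects only are tested; variance
  components enter through BIC).
* **Reproducibility**: every stochastic stage draws its seed from the
  global seed through a named substream hash, so regenerating one stage
  never perturbs another. Pipeline artifacts serialize numerics at 17
  significant digits (JSON and CSV), making rerun checksums exact.

## Known limitations

* The CLMM supports a single random intercept (no crossed or slope terms) —
  sufficient for the confidence analyses it serves.
* The generator's confidence, fixation-class mixture (share of
  "relevant-nondisplayed" among non-relevant fixations), and discrimination
  RT curves are plausibility choices, not fitted to data.
* Gamma-identity models can produce negative fitted means for extreme
  covariate values; the generator guards its own means but arbitrary user
  data may not.
* Perfect encoding accuracy is an in-sample
  property at these effect sizes; nested cross-validated accuracy is
  reported separately and is below 1 for the default (non-6-SD) world.
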