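# kinprime

Single-trial modelling of how reach-to-grasp kinematics **encode** an
agent's intention (pour vs drink) and how individual perceivers **read
out** that information — plus the downstream analyses linking readout to
**kinematic priming** of response times and initial fixations.

## Who this is for

Researchers studying action prediction from movement kinematics who need a
tested, reproducible implementation of the single-trial
encoding/readout framework and its priming analyses, with a calibrated
synthetic-data generator (known ground truth) for parameter-recovery and
power work.

## The models

Each reach is a 64-dimensional vector **K** (16 kinematic variables —
wrist velocity/height/horizontal trajectory, grip aperture, local-frame
thumb/index coordinates, finger- and dorsum-plane normals — averaged over
4 epochs of normalized movement time between the 20 mm/s velocity bounds).
Both core models are elastic-net (α = 0.95) logistic regressions on the
z-scored features, with the penalty chosen by leave-one-video-out
cross-validation:

- **Encoding**: P(intention = 'pour' | K) = σ(β·K + β₀), fit on the true
  intention labels — the information available to an ideal observer.
- **Readout**: the same model fit, per perceiver, on that perceiver's
  forced-choice judgments — the information that perceiver actually uses.

The **single-trial index** is the sign-adjusted linear predictor
y·(β·K + β₀), y = +1 for a true 'pour': the log-odds of a correct
classification, positive = correct, magnitude = information in log-odds
units. Per-variable contributions are the scalar products restricted to
each variable's epoch subspace (they sum to the bias-free predictor).
Priming analyses use gamma (identity link), logistic, and cumulative-link
mixed models: RT ~ probe × congruency × index with participant and prime
random effects, median-split priming effects, a zero-readout-prime
contrast, confidence ~ readout, and a pupil-baseline control.

## Worked example

```r
library(kinprime)
cfg <- kp_config(seed = 42)                      # the calibrated synthetic world
primes     <- generate_primes(cfg)               # 30 + 30 reaches, ground truth known
features   <- zscore_features(build_feature_matrix(primes))
perceivers <- generate_perceivers(cfg, primes$ground_truth$encoding_direction)

enc <- fit_encoding(features, primes$intention)
disc <- simulate_discrimination(primes, perceivers, cfg, features = features)
rd  <- fit_readout(subset(disc, perceiver_id == "s01",
                          c(perceiver_id, prime_id, choice)), features)

pt  <- simulate_priming_session(primes, perceivers, cfg, features = features)
ex  <- apply_exclusions(pt)
cim <- congruency_information_model(ex$trials, "true_readout_index", "rt")
ms  <- median_split_priming(ex$trials, "true_readout_index")
```

Output (seed 42):

```
encoding accuracy (in-sample): 1.00
top encoding variables: W_H, W_HT, DP_Y
perceiver s01: 2AFC accuracy 0.85, readout model performance 0.91
congruency x readout LRT: chi2(1) = 106.1, p = 7.2e-25
RT slope on readout: congruent -2.93, incongruent 2.57 ms per log-odds
priming effect: low readout -5.1 ms (p = 0.4), high readout 70.4 ms (p = 5.7e-28)
```

Reading it: the kinematics fully specify intention (encoding accuracy 1.0,
carried by wrist height W_H, wrist horizontal trajectory W_HT and
dorsum-plane y DP_Y); perceiver s01's choices are well captured by their
readout model (0.91) though only 85% accurate; and the more intention
information a perceiver reads from a prime, the faster (congruent) or
slower (incongruent) they categorize the following probe — priming is
large and significant for high-readout primes and absent for low-readout
ones.

## Pipeline and CLI

`run_pipeline(run_config(...))` executes simulate → features → encoding →
readout → priming end to end, writing CSV/JSON artifacts and an
MD5-checksummed manifest (identical config + seed ⇒ identical checksums).
The same stages are available from the shell:

```sh
Rscript -e 'kinprime::kp_cli()' simulate --out run1 --seed 7
Rscript -e 'kinprime::kp_cli()' analyze-priming --out run1 --seed 7
```

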