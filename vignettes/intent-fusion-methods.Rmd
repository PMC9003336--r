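---
title: "Modular Bayesian sensor fusion for intent classification: models, assumptions and design choices"
author: "intentfuse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular Bayesian sensor fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A body-worn sensor network for *intent sensing* tries to infer what a user
wants to do — here, which of three categories of reach/grasp activity they
have just begun — from passive multimodal measurements: surface
electromyography (sEMG, 1000 Hz) and inertial measurement units (IMUs,
60 Hz). In realistic use, sensors join and leave the network all the time
(devices are donned and doffed, batteries die, the user walks out of range).
A classifier trained on one fixed sensor combination cannot follow that
churn. The package implements and evaluates two approaches:

* **Modular method (MM).** One small classifier per sensor. Each sensor
  `s` produces its own prediction $V_s$, and the network combines them with
  Bayes' rule using per-sensor confusion matrices estimated on held-out
  data. For intent class $c$ with prior $P(c)$ and conditionally
  independent sensors,
  $$P(c \mid V) \;=\;
    \frac{P(c)\,\prod_s P(V_s \mid c)}
         {\sum_{c'} P(c')\,\prod_s P(V_s \mid c')},$$
  where $P(V_s \mid c)$ is read from sensor `s`'s confusion matrix. A
  sensor that drops out simply leaves the product; one that drops in just
  needs its own confusion matrix. No other sensor is retrained. For two
  classes this is exactly the familiar
  $P(E\mid V) = P(V\mid E)P(E) / (P(V\mid E)P(E) + P(V\mid E')P(E'))$.
* **Non-modular method (NMM).** One k-nearest-neighbour classifier over
  the concatenation of every sensor's features — representative of standard
  combined machine-learning practice. It cannot lose an input dimension, so
  a dropped sensor's features are replaced by the constant 0 that a dead
  channel would deliver.

The package's evaluation harness reproduces the three experiments that
separate the methods: accuracy as a function of the classification horizon
(how soon after activity inception the decision is made), accuracy as a
function of the number of sensors when the methods may train on exactly the
sensors present, and accuracy under random sensor dropout after training on
the full network.

## The synthetic data generator

The laboratory dataset this protocol was developed on (5 participants × 11
activities × 3 trials, 1000 ms horizon) is not redistributable, so
`generate_dataset()` emulates its statistical structure; every downstream
stage is testable without any download.

**sEMG model.** Each sensor produces a zero-mean broadband Gaussian carrier
amplitude-modulated by a smooth positive envelope built from logistic
ramps: a class-independent baseline burst plus category- and
activity-specific components. The category component is gated by elapsed
time $u = t/T$ and the activity component by a faster gate
$\min(u/0.6, 1)$: category divergence accumulates over the whole horizon
while within-category idiosyncrasies express early and saturate. The
divergence is scaled by the sensor's `informativeness` in $[0,1]$; at 0 the
signal is statistically independent of the class. MVIC references scale
the raw amplitudes; conditioning divides them back out.

**IMU model.** Orientation follows a minimum-jerk rotation about a
class-dependent axis (unit quaternions by construction); the accelerometer
reads gravity in the rotating body frame plus a sensor-specific dynamic
component and noise; the magnetometer is a fixed field rotated into the
body frame. Class information therefore grows monotonically with the
unfolding rotation.

**Correlated execution noise.** Every sensor watches the same physical
movement, so per-trial execution variability — expression strength
(`runif(0.35, 1)` scaling the class components), onset jitter
(SD 25 ms), pace and vigor — is drawn once per trial and shared across all
sensors. This is the crucial realism ingredient: with independent
per-sensor noise, two dozen sensors fuse to essentially perfect accuracy
and every comparison between fusion rules degenerates at the ceiling.
Shared execution noise produces correlated errors and bounds the
full-network accuracy near the realistic 0.9–0.97 range. Per-participant
random gains and offsets give the participant-balanced split something to
balance.

**Informativeness profile.** The default 24-sensor network (12 sEMG + 12
IMU) uses a fixed profile from 0.6 down to 0.02 per modality: most sensors
moderately informative, a couple nearly uninformative. The spread was
calibrated with the `class_separability()` diagnostic and small pilot runs
so that single sensors classify three categories well above chance but far
from perfectly (balanced accuracy mostly 0.35–0.7) — the regime where
confusion-matrix weighting and drop-in/drop-out behaviour actually matter.
A steeper profile makes the unweighted NMM fragile (its distance pools
noise dimensions), a flatter stronger one saturates both methods.

**What the generator does not emulate.** No motor-unit action potentials,
no soft-tissue artefact, no electrode lift-off, no magnetic disturbance, no
cross-talk between muscles. Passing tests therefore demonstrate the
*method's* properties (exact fusion algebra, dropout invariance,
monotonicity patterns) under plausible signal statistics — not performance
on real recordings.

`class_separability()` summarises each trial by its amplitude trajectory
(sEMG) or checkpoint samples (IMU) and sums per-dimension
between/within-class dispersion ratios, a diagonal Mahalanobis separation
of the class means. Extending the horizon appends dimensions, so the score
accumulates discriminative information over time; because even noise
dimensions contribute their null expectation, informativeness is judged
against the label-permutation distribution
(`separability_permutation_test()`), not against zero.

## Conditioning and features

* **Band-pass filter:** 10–500 Hz Butterworth, `order = 4` in the MATLAB
  `butter()` convention (the band-pass has 8 poles). At 1000 Hz sampling
  the 500 Hz edge sits exactly at Nyquist, where a digital design is
  undefined; the edge is clipped to `0.99 × fs/2` with a warning.
  Filtering is single-pass causal — consistent with eventual real-time
  use — and applied to sEMG only; IMU channels are used raw.
* **MVIC normalisation:** plain division by the per-muscle maximal
  voluntary isometric contraction reference.
* **Windows:** 200 ms segments stepped by 50 ms (150 ms overlap) inside
  the classification horizon; `floor((horizon − length)/step) + 1`
  windows, i.e. 17 at the full 1000 ms.
* **sEMG features** (per window): IEMG, MAV, VAR (as `sum(x²)/(N−1)`,
  the usual sEMG convention on effectively zero-mean segments), RMS, WL,
  autoregressive coefficients to order 4, and median/mean frequency from a
  single mean-removed periodogram. The named list also contains the mean
  absolute value slope (MAVS), a cross-window difference; the default
  `standard` preset drops it so each sEMG sensor contributes 11 within-window
  values, while the `full` preset keeps all 12 (MAVS of a trial's first
  window is defined as 0 so vectors keep constant length). AR coefficients
  come from the Burg recursion (`stats::ar.burg`) by default, switchable to
  explicit least squares — the estimator the test oracles replicate.
* **IMU features:** the raw orientation (4), accelerometer (3) and
  magnetometer (3) values of the last sample at or before the horizon —
  10 per sensor; a window-mean variant is config-selectable.
* **Standardisation.** Feature columns are z-scored per sensor at
  feature-bank assembly, using dataset-level, label-free statistics
  (`standardise = FALSE` restores raw units). The columns mix
  MVIC-normalised amplitudes, hertz and quaternion components; under an
  unscaled fractional Minkowski distance the hertz-scale spectral
  statistics dominate every distance for *both* methods and drive all
  classifiers to chance, so unit-free columns are the package default. For
  horizon sweeps the scaling is frozen at the full-horizon statistics
  (`extract_features(..., scaling =)`), so horizons differ only in the data
  they see.

## Classifiers

Both methods use 1-nearest-neighbour with the fractional Minkowski
distance $d(x,y) = \sum_k |x_k - y_k|^{0.5}$ (for neighbour ranking the
outer root is irrelevant). The "distance exponent 0.5" is implemented as
the Minkowski exponent — with one neighbour any kernel weighting of
neighbours is inert, so this is the only reading under which the exponent
changes behaviour. Exact distance ties resolve to the lowest canonical
training row (rows are sorted by trial id and window position at fit time),
which makes predictions invariant to training-row order.

Because trials are aligned at activity inception and the signal statistics
are strongly non-stationary, per-window queries are routed to training
segments of the *same window position* (`windowed_knn_fit()`): an
800-ms-deep segment is compared against other 800-ms-deep segments, not
against early segments whose amplitude happens to coincide. Pooling all
positions into one training set measurably destroys the per-window class
signal (in pilot runs, last-window leave-one-out accuracy fell from 0.67
to 0.44). The same construction is used for the combined NMM design
matrix, whose rows are windows with every sEMG sensor's features side by
side and per-trial IMU features repeated across windows.

A trial-level decision is the modal vote over its window predictions, with
ties going to the latest window (later windows have seen more of the
activity); a latest-window-only rule is available.

## Fusion

Confusion matrices are tallied on the Probability Learning half of each
training pool and row-normalised with an additive pseudo-count
(`smoothing = 1` by default): the learning sets are small (tens of trials
over 3 classes), and a single unsmoothed zero entry would annihilate the
posterior of any class a sensor has never been seen to confuse. A sensor's
overall accuracy is the diagonal mean of its row-conditional matrix —
balanced accuracy. Fusion accumulates log-probabilities (products over
dozens of sensors underflow), normalises, and takes the arg-max with ties
to the lowest class index; a tolerance of 1e-9 on the log scores makes the
tie rule immune to floating-point summation order. With no active sensors
the posterior is the prior (uniform by default; class-frequency priors are
config-exposed). Dropout is signalled by an explicit active-sensor set;
automatic dropout detection is out of scope.

## Evaluation harness

* **Protocol.** Leave-one-out over trials. For the MM, each fold's
  164-trial pool (at full scale) is halved into Classifier Training and
  Probability Learning sets, pseudo-randomly but balanced: every
  (participant, activity) stratum splits as evenly as possible and the
  marginal per-participant and per-activity counts differ by at most one
  (a greedy randomised assignment of odd-stratum leftovers, retried under
  fresh shuffles until the marginals hold). Five candidate splits are
  drawn and the one with the highest mean per-sensor balanced accuracy on
  its Probability Learning half is kept. The NMM trains on the full pool —
  it estimates no probabilities.
* **Horizon sweep:** truncate everything to the first X ms,
  X = 200..1000 in 50 ms steps, all sensors active; the trend is
  summarised by Spearman's rank correlation (average ranks for ties, the
  standard correction to the classical `1 − 6Σd²/n(n²−1)` form, which
  assumes none).
* **Sensor-count sweep:** for each R, both methods are trained on exactly
  the R sensors present, over random combinations; the MM re-selects its
  split for the subset, the NMM is restricted to the subset's columns.
* **Dropout sweep:** both methods train once on the full network; then N
  random sensors drop out. The MM removes them from the fusion and keeps
  the confusion matrices it already has; the NMM zero-fills their columns.
  The MM/NMM accuracy ratio per condition quantifies the relative benefit,
  with its range reported because it is not constant.
* **Combination sampling.** Random sensor subsets are nested: each random
  stream permutes the sensors once and takes the first N (or R), which is
  uniform at every size and lets the engine update distance-block sums
  incrementally as sensors enter or leave.
* **Intervals.** 95% t-intervals (`mean ± t₀.₉₇₅,ₙ₋₁·SE`) over
  combinations (sensor-count sweep) or over repetition means (dropout
  sweep); the construction is the standard small-sample choice and is
  switchable in principle to a normal approximation. The horizon sweep has
  no replication dimension and reports point accuracies.
* **Engine.** The sweeps run on an exact reformulation of 1-NN: the
  fractional distance is a sum of per-sensor column-block contributions,
  so restricting or zero-filling sensors is a sum over precomputed
  per-sensor distance blocks. The direct path
  (`optimise_split()`/`run_fold()` over `knn_fit()` and `fuse()`) is kept
  as the reference implementation, and the test suite asserts exact
  decision-level agreement between the two on both methods.

## Problem sizes

Package defaults follow the full protocol (165 trials, 50 combinations,
20 repetitions). The acceptance script and the heavier tests run the
package's desk-scale study conditions: 4 participants × 6 activities × 2
trials (48 trials, 3 categories), the default 24-sensor network, 10
combinations × 5 repetitions, chosen so the complete harness (three sweeps
with full leave-one-out and split optimisation at every fold) runs in a few
minutes while keeping the qualitative structure of the full protocol. At
these sizes the qualitative patterns the acceptance suite checks — rising
accuracy with horizon and with sensor count, NMM ahead without dropout, the
MM overtaking under heavy dropout with a monotonically growing accuracy
ratio — are stable for most generator seeds, but individual draws of the
class structure can produce datasets where the MM already leads at zero
dropout; the comparison between the methods is an expectation, not a law.

## Known limitations

* The generator's realism stops at feature-level statistics; conclusions
  about real sEMG/IMU recordings require real data.
* Sensors are conditionally independent given class, participant and the
  shared execution variables; real networks have richer cross-sensor
  structure that the NMM could exploit.
* The fractional-exponent distance and the absence/presence of feature
  standardisation interact strongly; the package documents and defaults to
  standardised columns, but no claim is made that this matches the
  original MATLAB pipeline's internals.
* Real-time operation (latency, streaming windows) is out of scope; the
  causal filter choice merely keeps the door open.
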