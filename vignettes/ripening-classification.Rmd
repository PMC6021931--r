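---
title: "Methods: ripening-stage classification from GC-MS profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripening-stage classification from GC-MS profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoripen)
```

# Overview

`eoripen` classifies essential oils into four fruit-ripening stages from
untargeted headspace GC-MS total ion chromatograms. This vignette is the
package's account of the method: the models, their assumptions, the
tunable parameters, the synthetic data the package tests itself on, and
the design decisions taken where more than one reasonable choice
existed.

# Chromatogram enhancement

## Log transform

Volatile abundances span orders of magnitude — a single limonene-like
peak can sit four decades above the minor peaks that carry most of the
class information. Each raw trace is therefore transformed as
`y = log10(I + offset)` with `offset = 1` intensity unit (intensities
are treated as arbitrary units throughout; the offset keeps
zero-intensity grid points finite). Base 10 is used so heights read
directly in decades.

## Adaptive asymmetric least squares baseline

The baseline `z` of a logged trace `y` minimizes

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$$

with second differences taken on the index grid (the acquisition grid is
uniform; non-uniform input would be interpolated first, which keeps the
penalty matrix pentadiagonal). The weights are iterated with the
peaked-signal asymmetric rule: points below the current baseline get
`1 - p`; points above it get `p * exp(-(y_i - z_i)/k)`, so large
positive residuals (peaks) are ignored almost entirely while small ones
still pull the baseline up. Parameters, all config-overridable via
`psalsa_params()`:

| parameter | default | units | role |
|---|---|---|---|
| `lam` | 1e5 | — | stiffness of the baseline |
| `p` | 0.001 | — | weight budget of above-baseline points (< 0.5 so the fit hugs the lower envelope) |
| `k` | 0.1 × range(y) | logged intensity | residual scale beyond which a point counts as "peak" |
| `max_iter` | 50 | — | weight-iteration cap |
| `tol` | 1e-3 | — | relative change of the weight vector at convergence |

The inner solve `(W + \lambda D'D) z = W y` is a banded Cholesky
factorization written in C++ (`src/banded.cpp`), O(n) per iteration; a
dense least-squares oracle in the test suite pins its correctness to
1e-8. On a constant signal the baseline reproduces the signal; on a
linear drift under isolated Gaussian peaks it recovers the drift to
under 2% of the drift range. Two properties of the estimator matter for
what follows:

- **Lower-envelope bias.** Under symmetric noise of standard deviation
  `sigma`, an asymmetric estimator settles near the bottom of the noise
  band, roughly `2.5 * sigma` below the noise mean, so corrected
  heights carry a small positive offset of that order. At realistic
  noise-to-baseline ratios this is far below one percent of a peak
  height in decades.
- **Ripple.** The smoothness penalty leaves a deterministic ripple of
  order 1e-3 logged units around very tall, narrow peaks. The detection
  threshold sits one to two orders of magnitude above it for any
  realistic noise level; it only becomes visible in artificial
  near-noiseless fixtures, which is why the test fixtures use a small
  but non-negligible noise floor (see below).

The pipeline applies the log transform first and the baseline second,
and peak heights are read on the logged, corrected scale.

## Noise statistics and the detection threshold

The detection threshold is the noise mean plus three times its standard
deviation. Noise is estimated from the *quiet region* of the corrected
trace — the `quiet_fraction = 0.2` of grid points with smallest
absolute intensity. Restricting to the central fifth of the noise
distribution truncates it, and the sd of that truncated sample
understates the full noise sd by a known factor under a normal model
(about 0.146 at 20%); `estimate_noise()` inverts that factor so the
threshold really is `mu + 3 * sigma` of the full noise distribution.
Monte-Carlo tests on pure Gaussian traces confirm the threshold lands in
`[2.5, 3.5] * sigma`.

# Peak detection and cross-run matching

A peak is a strict local maximum above the threshold; on a plateau the
leftmost point is the apex (a documented tie-break — the choice is
arbitrary but must be fixed for bit-reproducibility). The apex height on
the corrected logged scale is the feature value. Detection is
threshold-monotone: raising the threshold can only remove peaks.

With a `mu + 3*sigma` threshold, roughly 0.1% of grid points on a pure
noise trace exceed it at a local maximum. Those scattered false apexes
are individually harmless but collectively dense across hundreds of
runs: single-scale gap clustering at the cross-run tolerance (0.1 min)
would chain them into bridges between genuine compounds. `match_peaks()`
therefore clusters at two scales: first with the same greedy gap rule at
the acquisition-grid scale (`rt_resolution = 0.02` min, about two
sampling intervals at 2 Hz), discarding groups seen in fewer than
`presence_threshold` of the traces as irreproducible; then merging the
surviving groups whose gaps are within `rt_tol = 0.1` min. A real
compound appears at essentially the same retention time in every run and
survives; noise apexes appear in one run each and do not. With a single
trace, or with noise-free detections, the two-stage rule reduces exactly
to the single-scale rule.

The default `presence_threshold = 1` registers only peaks present in
every chromatogram. Traces missing a registry peak (possible at lower
thresholds) are imputed at that trace's own detection floor and flagged.

# Classification under double cross-validation

## Split design

Oils (not traces) are randomly assigned, per class, to training (70%),
internal validation (10%) and external validation (the remainder), with
counts rounded to nearest (half up). All replicate injections of an oil
share its subset — anything else would leak replicate identity into the
external assessment. For the reference class sizes 11/27/36/27 this
yields 19 of 27 second-class oils in training and 19 external oils in
total; descriptions of the original design are internally inconsistent
about whether the external set held 19 or 20 oils, and the rounding
convention here is the one that reproduces the printed 19-of-27 training
example.

## The network and its trainer

The classifier is a multilayer perceptron with one or two sigmoidal
hidden layers (hyperbolic tangent or logistic), four *linear* outputs,
one-hot class targets, and a least-squares objective. Training is
full-batch resilient backpropagation (Rprop): per-weight step sizes grow
by 1.2 when the gradient keeps its sign, shrink by 0.5 when it flips
(with the flipped gradient sign forgotten, the iRprop- variant), bounded
to `[1e-6, 50]`, initial step 0.1. Rprop only uses gradient signs, so it
is insensitive to the scale of the least-squares loss. Weights
initialize from `N(0, 1/sqrt(fan_in))` under a per-fit seed; features
are z-scored with the mean and sd of the *training rows only*.

Early stopping monitors the internal-validation CCR with a patience of
30 epochs (cap 200) and restores the best-scoring weights. After model
choice, the network is refit on the fused training + internal data for
the epoch count the monitored fit reached, and only then scored on the
untouched external subset. The early-stopping criterion of the original
work is unstated; validation-CCR patience is this package's choice.

## Architecture search

Candidates (default ladder: widths 2/4/8/13/16, one or two layers, both
activations) are scored by mean internal-validation CCR over the same
set of partitions. The winner is the highest mean; candidates within one
standard deviation of the winner are treated as equivalent and the tie
breaks towards the fewest trainable weights. CCR is computed over
replicate-level rows (303-row semantics); an oil-level majority-vote CCR
is reported alongside but never drives selection.

The reference analysis used 1000 random partitions; the package defaults
to `R_partitions = 20` in `pipeline_config()` and the tests use 10-50,
which is enough to estimate a CCR mean to a few points while keeping a
full test run in minutes. `R` is a plain argument everywhere, so full
fidelity is one keystroke away.

# Sensitivity analysis and sequential feature addition

The sensitivity of input `j` for class output `c` is the range (max
minus min) of output `c` as input `j` sweeps `grid_steps = 50` equally
spaced values across its observed range with all other inputs locked at
their column means. A single non-negative number per input and class is
wanted for ranking, and the response range is the simplest statistic
consistent with that; 50 steps resolves the sigmoidal response shapes at
negligible cost. Sensitivities are averaged over the per-partition
models by default (`use = "average"`); `use = "best"` reproduces the
single-best-network reading.

Peaks are ranked per class by descending sensitivity (ties towards the
smaller peak id), and the input set grows by *sequential rank addition*:
the rank pointer advances to the lowest rank whose union of per-class
peaks contributes at least one new peak, and all such new peaks join as
one step; rank levels contributing nothing new are skipped without
producing a step. This skip-rank semantics is the only reading that
reproduces the published 13-step addition table from the published
rankings, including the step-8 set of 15 peaks — the package carries
those rankings (`bitter_orange_rankings()`) and the test suite asserts
the exact reconstruction. An equivalent closed form — each peak joins at
its best rank across the four classes — serves as the independent oracle
in property tests.

Each step's cumulative peak set is re-evaluated under the full double
cross-validation with the winning architecture (input layer resized);
the best step is the highest mean internal-validation CCR, ties towards
fewer peaks.

One caveat carried over from the source material: the prose listing of
the selected compounds and the addition table disagree about two peak
numbers (an internal numbering inconsistency); the package trusts the
tables, which are self-consistent.

# Permutation significance test

Class labels are permuted at the oil level (replicates keep one common
permuted label; class sizes are preserved by construction and asserted
on every draw). For each permutation the cross-validated external CCR is
recomputed and its mean recorded; the observed distribution comes from
the real labels. By default the architecture found on the real labels is
reused for the null runs (`search_space = NULL`); passing a search space
repeats the architecture search per permutation at full cost. Null runs
default to fewer partitions (`R_null`) than the observed runs: the
statistic is a distribution comparison and its location is insensitive
to that scaling, which is what makes hundreds of permutations tractable
on one CPU.

The two CCR samples are compared with a Mann-Whitney U test implemented
in-package: `U` counts pairs with `a > b` (ties half), computed via
midranks; the p-value is exact by enumeration over all group assignments
of the pooled values when `n_a * n_b <= 400` (and the enumeration is
small enough), otherwise a normal approximation with tie and continuity
correction. The exact branch agrees with a brute-force oracle to 1e-10
in the tests; the normal branch matches `wilcox.test` on tie-free data.
An empirical p-value `(1 + #{null >= mean(observed)})/(1 + n_perm)` is
reported alongside. The default is two-sided; the reference analysis
states only a rejection level, so sidedness is left to the user.

# The synthetic data generator

The generator is first-class, tested code — it defines the study
conditions under which the pipeline's statistical claims are verified.
`default_peak_specs()` fixes 22 Gaussian peaks at the retention times of
the compounds consistently found in bitter-orange headspace (1.99 to
26.07 min), with widths 0.04-0.12 min chosen so every neighbouring pair
stays baseline-resolved — the 8.27/8.41 min pair, 0.14 min apart, forces
0.04 min there for apex heights to be clean to 1%. One peak (limonene,
10.45 min) sits more than two decades above all others and is
deliberately uninformative; 15 peaks carry the class signal with
increasing, decreasing or U-shaped (equal first and last stage)
trajectories of amplitude 0.25 decades (0.35 for the three leading
peaks), echoing the non-monotone evolution of monoterpenes during
ripening.

A trace is `baseline + sum of Gaussians * 10^(class log height + oil
effect + replicate effect) + N(0, noise_sd)` on a uniform grid over
0.5-28 min at 2 points per second. The baseline is a gentle linear
drift plus one broad cosine (about ±10% around its amplitude), strictly
positive. Defaults: `noise_sd = 2` and `baseline_amplitude = 50`
(arbitrary units; the smallest peak still clears the detection threshold
by an order of magnitude, as in the reference data where all 22 peaks
were consistently detected), between-oil scatter `eo_log_sd = 0.15` and
within-oil `replicate_log_sd = 0.05` decades — typical magnitudes for
headspace sampling of replicate aliquots. The `separability` knob scales
the between-class log-height differences: 0 removes all class signal
(for chance-level calibration), 1 is the default study, 2 is the
"high-separability" condition used in the accuracy tests.

What the generator deliberately does **not** emulate: retention-time
drift between runs (the matching tolerance is exercised only by noise
jitter), co-elution and peak-shape asymmetry, heteroscedastic detector
noise, per-compound biological scatter (oil effects shift all peaks of a
trace together, so the within-class variability of the *pattern* is
optimistic compared with real biology), and mass-spectral information of
any kind. Passing tests therefore demonstrate the pipeline's
correctness and calibration, not field performance on real oils — the
headline accuracies of the original study are not reproducible without
its raw data, and the package makes no attempt to imitate them.

# Numerical and testing choices

- All randomness flows from explicit integer seeds; per-partition,
  per-fit and per-permutation seeds are drawn deterministically from the
  master seed, so every pipeline artifact is bit-reproducible.
- Degenerate inputs: designs with non-positive noise are rejected;
  classes too small to populate every requested subset raise an error;
  zero-variance feature columns standardize to zero with a warning;
  identical pooled samples give a Mann-Whitney p of 1.
- Test problem sizes: module tests run studies of 8-96 traces and
  cross-validations of 2-12 partitions; the acceptance-style tests use
  the full 303-trace default study for registry recovery, 50 partitions
  for the chance-band calibration, and 99 permutations (100 repeats at
  reduced partition counts) for the p-value calibration. These sizes
  estimate each quantity to well inside its asserted band; all scale-up
  knobs are ordinary arguments.
- The near-noiseless test fixtures use `noise_sd = 0.003` rather than a
  strict zero: the detection threshold then sits above the baseline
  ripple left around tall peaks while apex heights stay exact to well
  under 1%.

# Limitations

- No retention-time alignment: the matching stage assumes RT stability
  within `rt_tol` across runs, adequate for a single-instrument study
  but not for multi-batch data.
- No peak-area integration or deconvolution; heights of overlapping
  peaks would be biased.
- The Levenberg-Marquardt trainer explored in the original work is not
  implemented; resilient backpropagation (the better performer there) is
  the trainer.
- Compound identities attached to peaks are metadata only; nothing in
  the pipeline uses mass spectra.
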