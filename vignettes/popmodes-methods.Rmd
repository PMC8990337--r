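---
title: "Activity modes, latencies and hierarchical inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity modes, latencies and hierarchical inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmodes)
```

This vignette is the package's account of its methods: the statistical
model behind each estimator, the defaults and why they are what they are,
what the synthetic-data generator does and does not emulate, and the
numerical decisions a maintainer would want written down.

## 1. The task and the data model

A delayed-response trial has three epochs: a *sample* epoch (1.4 s) in
which the instruction is delivered, a *delay* epoch (1.2 s) in which the
animal plans a directional lick while holding still, and a *response*
epoch (1.5 s) opened by an auditory go cue. All peri-cue analyses place
`t = 0` at the go cue; bins are half-open `[t, t + dt)`, so every spike
belongs to exactly one bin.

A `session_data` object holds one recording: unit metadata with sorting
quality metrics, a long spike table (seconds, session clock), and a trial
table with event times, trial type (`lick_right` / `lick_left`), outcome
(`correct` / `incorrect` / `no_response` / `early_lick`) and perturbation
labels. Early-lick trials are excluded from every analysis unless asked
for explicitly. The on-disk format is a directory of plain CSV tables plus
a JSON identity file; round trips are lossless.

## 2. Activity modes

All modes are *difference-defined* unit vectors in the `n`-dimensional
neuron-activity space (see the README for the definitions and windows).
Two disciplines are enforced throughout:

* **Train/test split.** Directions are estimated on a random half of the
  unperturbed correct trials (type-balanced, seed-reproducible); held-out
  trials are only ever projected. A property test verifies that perturbing
  held-out spikes cannot change a mode's weights.
* **Explicit orthogonalization.** `CD_response` is Gram–Schmidt
  orthogonalized to `CD_delay`; `orthogonalize_set()` orthogonalizes a
  full set sequentially. The default order is
  `CD_delay -> CD_response -> D_go -> D_ramp`: the pairwise order of the
  two coding directions is fixed by their definitions, and the remaining
  order is a package choice (exposed as an argument) that puts the
  better-determined, behaviourally primary directions first so that later,
  noisier directions absorb the residual. Gram–Schmidt output is tested
  against the QR factorization of the same vectors.

Degeneracy is decided on a scale-free criterion: a vector counts as zero
when its norm is below `1e-9 * sqrt(n)` (i.e. 1e-9 per-coordinate RMS);
such cases raise a classed `popmodes_degenerate` error naming the mode
rather than returning garbage.

**Session normalization.** To pool sessions, projections are mapped to a
common scale using anchors computed from the *training* means only:
lick-left pre-cue mean to 0 and lick-right to 1 for `CD_delay` (100 ms
window; 400 ms post-cue window for `CD_response`), and pre-cue mean to 0
with the pre-to-post change equal to 1 for `D_go`. Anchors whose
denominator is below tolerance mark the session non-normalizable
(`popmodes_ineligible`), mirroring the eligibility gate below. Whether
anchors should be recomputed per bootstrap iteration is not determined by
the procedure itself; the package recomputes them per iteration (each
iteration is a fresh session sample), and passing stored `anchors`
freezes them instead.

A point worth knowing about difference-defined directions: because the
direction is chosen to maximize the very contrast it is later evaluated
on, the training-set contrast overestimates the population value, and
held-out projections shrink toward zero by roughly
`||signal||^2 / (||signal||^2 + n * sigma^2)` (regression to the mean).
With ~40 trials per type the held-out `D_go` change is visibly below its
training anchor; with ~120 trials per type the shrinkage is within a few
percent (the acceptance script reports the held-out change under
`dgo_heldout_change`). This is a property of the method, not a bug, and is
the reason the normalization-transfer check runs at the larger trial
count.

**Eligibility.** Sessions enter mode estimation only with at least five
analyzable cells and significant pre-cue selectivity (two-sided rank-sum
on per-trial projections onto the pre-cue rate-difference pattern, 100 ms
window, `p < 0.05`). Units with session-mean rate below 2 spikes/s over
the analyzed trials are excluded first; the threshold is evaluated on the
analyzed (correct, unperturbed) trials before subsampling, and the
boundary value 2.0 is kept (strict `<`). Both rules are logged per
excluded entity — the many exclusion rules are the main reproducibility
hazard of this kind of pipeline, so `run_analysis()` records every one
with the rule that fired.

## 3. Latency estimation

**Single neurons (two-step Poisson).** Spikes of 40 subsampled correct
trials per type are pooled in 1 ms bins. The tested statistic is the
count in consecutive non-overlapping 5 ms analysis bins. Two numerical
decisions matter here:

* *Test.* The default per-bin test is the exact conditional binomial
  comparison of the bin count with the pooled pre-cue baseline count
  (`k | k + N ~ Binomial(k + N, w/(B + w))`), which stays exact when the
  baseline rate is itself estimated; the plug-in exact Poisson tail
  (`baseline_method = "plugin"`) treats the baseline as known and is
  anticonservative at realistic baseline counts.
* *Binning.* With per-millisecond tests at `alpha = 0.001`, a 200 ms
  search window performs ~200 quasi-independent comparisons and the
  familywise false-positive rate cannot stay below 5%. Aggregating to 5 ms
  bins (the same width used to smooth peri-cue rates) keeps the empirical
  null false-positive rate at ~2% while recovering planted step latencies
  to within 2 ms (both quantities are recomputed by the test suite and the
  acceptance script). `test_bin_ms = 1` restores per-millisecond tests.

The latency itself follows the two-step rule: `T_p001` is the first
post-cue bin significant at `alpha = 0.001`; the latency is the earliest
bin of the contiguous run, significant at `alpha = 0.05` in the same
direction, that contains `T_p001`. The alternative literal reading — the
latest significance onset at the 0.05 level before `T_p001` — is
implemented behind `rule = "literal"`; the two coincide whenever the run
containing `T_p001` is unbroken, which a test asserts on constructed
count paths. Downward latencies are reported as absent (with a reason)
when the baseline is too low for a decrease to ever reach significance.

**Areas.** The area latency is the time by which at least 1% of all
analyzed cells — non-responders in the denominator — have an upward
latency; the s.e.m. comes from a 1000-fold bootstrap over cells. The
denominator uses all post-quality-filter cells (the analyzed population),
since including only responders would make the statistic independent of
the responder fraction. The estimate is monotone non-decreasing in the
fraction by construction.

**Projections.** Projection traces are standardized by the mean and s.d.
of the 100 ms before the cue (strictly `t < 0`), smoothed with a causal
10 ms boxcar, and scanned: first |z| crossing of 5 s.d. defines `T_std5`,
and the latency is the start of the contiguous |z| >= 2 s.d. run containing
it. Isolated early blips above 2 but separated by a sub-threshold gap are
excluded by the contiguity rule.

**Kinematics.** Jaw/nose onsets: per bootstrap draw, the trial-mean trace
is linearly detrended on the last 0.6 s of the delay and the onset is the
first post-cue sample exceeding 3 baseline s.d. (100 ms window). Tongue
onsets: the first time the c.d.f. of post-cue tongue detection times
exceeds the cue-omitted c.d.f. by 0.05. One caveat is worth recording:
the 3-s.d. rule tests every post-cue sample, so on traces whose noise is
temporally *white* a fraction of draws will cross threshold before any
real movement; real tracking noise is strongly autocorrelated and the
trial-mean traces are smooth, which is why the rule works in practice.
The recovery checks therefore use movement amplitudes well above the
noise floor, where the planted 64 ms onset is recovered to within 10 ms.

## 4. Resampling inference

`hierarchical_bootstrap()` resamples animals with replacement, then
sessions within each sampled animal, then trials within each sampled
session, and evaluates the statistic on each of 1000 draws. One-sided
p-values are the fraction of draws consistent with the null, floored at
`1/n_iter` (a bootstrap cannot certify a p-value below its own
resolution). With a single animal and session the scheme reduces exactly
to the flat trial bootstrap, which a distributional test verifies. On
three-level Gaussian data at 12 animals x 4 sessions x 20 trials the 95%
percentile CI covers the truth in ~92% of replications — slightly below
nominal, as expected for percentile intervals with a modest number of
top-level clusters — and null p-values are indistinguishable from uniform.

Rank-sum tests use exact enumeration below 10 observations per group and
the tie-corrected normal approximation otherwise; decoding uses the rank
(Mann–Whitney) AUC with mid-ranked ties, which is invariant under strictly
monotone transforms. Trial-by-trial mode correlations are computed *within
a trial type*: across pooled types, the selectivity itself correlates
pre- and post-cue projections regardless of any shared gain, so the
within-type correlation (with a trial-shuffled twin as control) is the
meaningful statistic. The logistic lick model is an IRLS binomial fit
(deviance tolerance 1e-8, max 100 iterations) on internally standardized
covariates, with complete separation flagged when any standardized
|coefficient| exceeds 15. Density maps smooth neuron locations with a
Gaussian of 250 um half-width at half-maximum
(`sigma = 250/sqrt(2 log 2)` um, kernel value 1 at distance 0) and divide
flagged by total smoothed counts plus the 0.05 regularizer. Fisher LDA
uses the closed-form pooled-scatter solution with the threshold at the
midpoint of the projected class means (equal priors).

## 5. The synthetic-data generator

`simulate_session()` draws spikes by 1 ms Bernoulli thinning of a
deterministic rate model (rates are far below 1000 spikes/s, so thinning
at that resolution is exact for practical purposes and bit-reproducible
from the seed). Per unit the rate combines, each clipped at zero only
after summation:

* a baseline (uniform on 2–10 spikes/s);
* a non-selective linear delay ramp (0–6 spikes/s) and, for half of the
  units, a direction-selective ramp (4–12 spikes/s, random sign) — the
  preparatory activity; after the cue the ramp decays exponentially
  (tau 0.15 s), emulating the collapse of planning activity. The rate
  model's contract defines the ramp only up to the cue; the decay is the
  package's choice of post-cue behaviour;
* for 60% of units a transient cue response: a causal alpha-function
  kernel (tau 15 ms) with planted latency (Gaussian, mean 20 ms, s.d.
  6 ms), amplitude 5–25 spikes/s, 25% of cue-responsive units go *down*;
  its direction modulation is small (0.05–0.2), because the go-cue
  response is close to condition-invariant;
* for half of the units a sustained, direction-selective response-epoch
  component (4–12 spikes/s, saturating onset tau 50 ms, decay tau 0.6 s):
  the movement-command selectivity that `CD_response` captures. Together
  with the selective ramp this plants a rank-2 selectivity structure with
  linearly independent delay and response patterns.

A single lognormal gain (`sd` parameter 0.2, i.e. ~20% trial-to-trial
coefficient of variation, a realistic cortical gain dispersion) multiplies
all non-baseline components of *all* units within a trial. This one knob
produces the trial-by-trial coupling between delay- and response-epoch
activity that the downstream correlation analysis must detect; setting
`gain_sd = 0` removes it, which the acceptance checks use as the negative
control. No-response trials attenuate the gain (x 0.4); stimulation trials
scale the cue kernel by `perturbation_scale`; cue-omitted trials have no
cue kernel and no movement. Quality metrics are drawn independently of the
firing model, with a configurable fraction of units planted to fail
exactly one criterion, so filter logic is testable against known flags.

Kinematic traces are white Gaussian noise plus per-trial linear drift plus
a causal saturating displacement from the planted onset (64 ms) on
movement trials at 400 Hz; tongue detection times add exponential jitter
(mean 30 ms).

`planted_mode_patterns()` evaluates the noise-free rate model itself to
produce the reference directions for recovery scoring, so the ground-truth
side of every recovery check is independent of the spike-based estimators.

**What the generator does not emulate.** Rates are conditionally Poisson
(no refractoriness, bursting or history dependence); noise correlations
beyond the single shared gain are absent; selectivity patterns are fixed
within a session (no drift); kinematic noise is white rather than
autocorrelated; and the planted parameter values are calibration choices
in the regime the modeled system describes, not estimates fitted to any
recording. Passing the recovery checks therefore demonstrates that the
estimators recover the structure they are defined to measure at realistic
signal-to-noise — not that real data contain exactly this structure.

## 6. Problem sizes and determinism

The test and acceptance workloads are sized to run comfortably on one
CPU: single sessions of 100 units x 40 trials per type for mode recovery,
200 simulated units (plus 1000 nulls) for latency recovery, 3 x 300 cells
for area ordering, 200 replications x 1000 bootstrap iterations for CI
calibration, and 300 trials for kinematic onsets. Every stochastic
function takes a seed and derives child seeds deterministically below
2^31; `run_analysis()` is a pure function of its config — re-running it
byte-reproduces every artifact, which the test suite asserts.

## 7. Known limitations

* Modes are subtraction-defined directions; no demixed-PCA/TDR-style
  alternatives are provided, by design.
* The two-step latency test reports latencies on the 5 ms analysis grid;
  sub-bin timing requires `test_bin_ms = 1` and correspondingly stricter
  interpretation of single-unit false positives.
* Percentile hierarchical-bootstrap CIs undercover mildly with few
  animals; with very few top-level clusters a different interval (e.g.
  BCa over clusters) would be needed.
* The 1%-of-cells area latency is an extreme order statistic: with a few
  hundred cells it is sensitive to single false-positive units, which is
  why end-to-end area comparisons need either thousands of cells (as in
  large-scale recordings) or the planted-latency route used in the tests.
* NWB ingestion is not provided; sessions enter through the documented
  CSV directory format or in memory.
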