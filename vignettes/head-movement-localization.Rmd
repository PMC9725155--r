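---
title: "Head movement and accuracy in horizontal auditory localization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head movement and accuracy in horizontal auditory localization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audioloc)
```

# The analysis problem

In a pointing-based localization experiment, a listener hears a stimulus
from one of 13 loudspeakers spanning the frontal hemifield (−90° to +90°
in 15° steps) and points at the perceived source while a head-mounted
tracker records the 3D head position and orientation quaternion at a
nominal 10 Hz. Each participant completes 65 trials (13 targets × 5
repetitions) per condition; two conditions are run — real (loudspeakers
visible) and virtual (vision replaced by an uninformative virtual
landscape) — and participants are split into two groups by condition
order (`G_R` starts real, `G_V` starts virtual).

`audioloc` derives, per trial:

* **signed error** — pointed minus target azimuth, wrapped to
  (−180°, 180°]. Under the package's rightward-positive convention a
  positive mean is a rightward response bias. Note the sign choice:
  "target minus pointed" definitions exist in the literature, but with a
  rightward-positive azimuth axis only `pointed − target` makes a
  positive value read as a rightward shift, which is the quantity of
  scientific interest here.
* **unsigned error** (ε) — the absolute error, the accuracy measure.
  Because the pointer resolves 1°, ε is analysed in 1°-wide bins
  centered on integers (half-open, `[c − 0.5, c + 0.5)`).
* **latency** — `t_hit − t_onset` in seconds, with no reaction-time
  floor.
* **head divergence** — target azimuth minus head yaw at the sample
  nearest the response (ties to the earlier sample; no interpolation,
  since at 10 Hz any interpolation model is unverifiable). Yaw is
  extracted by rotating the forward vector with the quaternion and
  projecting onto the horizontal plane, avoiding Euler-order ambiguity;
  orientations within numerical precision of straight up/down have no
  yaw and raise a classed degenerate-orientation error.
* **head distance** (h) — cumulative Euclidean path length of the head
  position over `[t_onset, t_hit]`, in meters. This is the head-dynamism
  measure. Positions are summed raw; an optional `min_step` threshold
  exists for noisy trackers but defaults to 0.

# Outlier filter

Trials whose unsigned error exceeds `mean + 2·SD` (sample SD, strictly
greater) of their stratum are flagged, not deleted. The stratum is the
target location within each condition, pooled across participants and
groups. The pooling level is a genuine design choice: "per target
location" fixes the finest axis, but whether to pool over conditions is
open — pooling across conditions would mix the tighter real-condition
error scale with the broader virtual one, so the default keeps them
separate, and `fully_pooled` / `per_participant` remain available as
options. "Deviation" is read as the unsigned error (the accuracy
measure), the natural argument of an accuracy filter.

# Inferential battery

All tests are two-tailed at α = 0.05. For each comparison of two cells
the battery runs Levene's test first; if homogeneity of variance is not
rejected the means are compared with the classical one-way ANOVA F,
otherwise with Welch's t (Welch–Satterthwaite dof). Correlation uses
Spearman's ρ (average ranks; equivalent to Pearson on ranks) because
none of the measures is assumed normal. Levene centering is the
classical mean-centering; median centering (Brown–Forsythe) is exposed
as an option because common toolchains default to it and the naming in
reports is often loose.

Bonferroni families must be declared explicitly: `bonferroni(p, m)`
takes the family size as an argument and the battery records the `m` it
used (4 per measure: two between-group and two between-condition
comparisons). Post-hoc power is computed from the observed standardized
effect via the noncentral t (two samples, `df = n1 + n2 − 2`) or
noncentral F (one-way); with a zero effect it equals α exactly. Observed
effects are the only basis available for post-hoc power, and its
well-known circularity is the reason it is reported but never used for
inference.

The eccentricity regression fits an OLS line to the per-azimuth *means*
of a measure (at most 13 points), not to raw trials: it quantifies how
central tendency scales with target eccentricity. With the package's
sign convention an undershoot (responses biased toward the midline)
appears as a *negative* slope of signed error against azimuth; the
undershoot magnitude is the negated slope. When the response means have
zero variance, r² is defined as 0 rather than left undefined.

# Envelope analysis

The coupling between head distance and accuracy is triangular: large h
occurs only at small ε, while small h occurs everywhere. The package
makes this quantitative three ways:

1. **Binned upper confidence bounds** — per 1° ε-bin,
   `mean(h) + k·SD(h)` with k = 1.96 ("95") and k = 3 ("99.7", i.e.
   three SDs above the mean). Bins with fewer than 2 points have no
   sample SD and are excluded (and reported). The bounds are then fitted
   by unweighted OLS, both linearly (`h ≈ m·ε + q`) and after a
   logarithmic transform (`h ≈ A·log(max + 1 − ε) + B`, natural log,
   where `max` is the data set's largest unsigned error so the argument
   stays ≥ 1). The log base only rescales `A`; natural log is the
   package's fixed choice. OLS is unweighted across bins because no
   weighting scheme is canonical here; a count-weighted option exists.
2. **Quadrant-partition frontier** — for each candidate corner abscissa
   `eps0` (swept over the sorted unique ε), the ordinate `h0` is the
   k-th largest h among trials with `ε ≥ eps0`, `k = round(0.05·N)`
   (minimum 1). Each closed quadrant `{ε ≥ eps0, h ≥ h0}` then contains
   exactly k points when the tail distances are distinct; with ties it
   contains the smallest attainable count ≥ k. The corner is closed
   (≥ on both axes) because only a closed corner makes the count
   achievable exactly in the distinct case. `h0` is provably
   non-increasing in `eps0` (the k-th largest over a subset cannot
   exceed the k-th largest over its superset), and the sweep terminates
   once fewer than k points remain.
3. **Quartile split** — trials are split at the third quartile of head
   distance (type-7 linear interpolation between order statistics) and
   the head divergence of the high-movement side is compared with the
   rest: the reported percentages are the relative shrinkage of the
   absolute mean and of the SD. Positive values mean high-movement
   trials end with the head better aimed at the source.

# The synthetic-data generator

No public per-trial data exists for this class of study at desk scale,
so the generator is a first-class, tested module that emulates the
statistical structure the pipeline must detect; every test involving
data runs against its known truth.

Per trial the generator draws a **strategy**: with probability
`p_dynamic` (default 0.3, optionally per condition) the trial is an
active head search, otherwise static. The response is
`target·(1 − undershoot) + bias + noise`, rounded to 1° *after* noise
(matching the pointer resolution), with undershoot slope 0.03, a
group-by-condition rightward bias of 1.93/2.47/1.74/0.60° and noise SD
1.5° on dynamic trials versus 2.8° (real) / 4.9° (virtual) on static
ones — the mixture that generates the triangular region without
asserting any causal law (movement is sufficient, not necessary, for
accuracy). Latency is lognormal with means anchored at
2.99/3.69/3.50/4.27 s by group and condition and `sdlog = 0.45`, a
typical response-time dispersion chosen once (no latency SDs are
available as anchors).

Head orientation relaxes from straight ahead toward the target along a
damped exponential (time constant 0.3–1.0 s, capped at a quarter of the
latency so the endpoint is reached), ending at a drawn divergence from
the target: N(0°, 8°) for dynamic trials, N(0.5°, 21°) for static ones.
Two modeling points deserve emphasis:

* *Static heads still orient partially.* If static trials kept yaw at
  0°, divergence would equal the target azimuth and its SD would be
  ~56°, far from the ~20° spread such studies report. The generator
  therefore treats divergence as the drawn quantity for both
  strategies; what distinguishes a static trial is that the head
  *translates* only by slow postural sway, while dynamic trials sweep
  an arc of radius `pivot_radius` (0.09 m, a neck-pivot lever arm) plus
  a decaying search oscillation.
* *Tracker noise is sway, not white noise.* Submillimeter trackers
  justify a ~2 mm amplitude, but i.i.d. 2 mm noise at 10 Hz would add
  ~0.1 m of spurious path length per trial and erase the triangular
  region. The generator uses low-frequency (0.1–0.5 Hz) sinusoidal sway
  with amplitude `jitter_sd` instead, which contributes millimeters of
  path, matching how a seated head actually drifts.

An optional head–pointer coupling (`n_coupled`, default 0) makes the
signed error of selected virtual-first participants depend on their
drawn divergence (`coupling_gain` 0.25° per degree), emulating listeners
who point where their head ends up; it is off by default because it is
an individual strategy, not a population-level condition.

All draws flow through one RNG stream seeded from `cfg$seed`
(Mersenne-Twister, inversion), so datasets are bitwise reproducible.
Balance is exact by construction: each azimuth appears exactly `reps`
times per participant and condition via a seeded shuffle of the
replicated target list.

What the generator does *not* emulate: acoustic cues (ITD/ILD/HRTF),
front–back confusions (targets are frontal only), torso/eye
decomposition, learning or fatigue dynamics, and any trajectory-shape
realism beyond a smooth approach (no public per-trial trajectory
statistics exist to calibrate against). Passing tests therefore
demonstrate that the pipeline recovers structure *of this kind* from
data *of this form* — not that real listeners behave like the model.

# Numerical choices and degenerate inputs

* Angles wrap into (−180°, 180°]; the wrap is applied to differences
  (divergence, signed error) so −345° and +15° are the same miss.
* Quaternions must be unit: readers renormalize deviations ≤ 1e−3
  (tracker rounding) and reject anything larger; yaw extraction demands
  1e−6 and raises a classed error for vertical gaze.
* Sample SD (`ddof = 1`) everywhere; strata/bins/cells needing an SD
  require n ≥ 2 and warn or are excluded otherwise.
* r² is defined as 0 for zero-variance responses.
* Q3 uses quantile type 7; `yaw_at_hit` tolerates `t_hit` one nominal
  sample period outside the sampled window (the response trigger and the
  tracker are not synchronized).
* The outlier percentage is emitted both raw and rounded to 2 decimals,
  because a truncated display value cannot be recovered from a rounded
  one.

# Problem sizes used by the test suite

The suite exercises the full default study (37 participants, 4810
trials) once, reusing it across tests; the 50-seed parameter-recovery
sweep runs on a reduced study (6 participants, 2 repetitions, 312
trials per seed), which is ample for Monte-Carlo confidence intervals on
the injected bias, undershoot and envelope-slope sign. Null-calibration
of the battery uses 1000 replicates of 3 × 20 observations. These sizes
are the package's own choices for a fast, deterministic suite.

# Known limitations

* The envelope bounds assume enough points per 1° bin to estimate an SD;
  sparse high-error bins are dropped, so fitted envelopes describe the
  populated error range only.
* Post-hoc power from observed effects is reported for completeness but
  is a biased estimate of true power.
* The quadrant frontier's "exactly k" guarantee holds for distinct
  distances; heavy ties (e.g. quantized h) yield the smallest count ≥ k.
* The generator's strategy mixture is the simplest process that produces
  the triangular coupling; it should not be read as a cognitive model.
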