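---
title: "Methods: age- and diet-associated metabolome remodeling"
author: "metaboaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age- and diet-associated metabolome remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboaging)
```

# The analysis in one paragraph

Untargeted LC-MS profiling of aging *Drosophila* cohorts on a standard and a
lifespan-extending defined diet produces a feature-by-sample intensity table
in which an intensity of exactly 0 means "below the detection limit". Two
distinct signals live in such a table. First, the *set* of detected features
grows with age — metabolite diversity rises and then levels off near the
ages where mortality accelerates — which this package quantifies as
per-sample detected counts, a cubic trend over age, and the age at which the
fitted trend's derivative first vanishes with negative curvature. Second,
among features detected in every sample, a minority change their *levels*
systematically with age; these are found with a per-feature one-way
repeated-measures ANOVA, compared across diets (overlap, trajectory
concordance against a re-pairing permutation null, fold changes), grouped by
complete-linkage hierarchical clustering into k = 12 trajectory clusters,
classified as diet-independent / progressive / intermittent, and summarized
as remodeling-delay curves showing that the long-lived diet traverses the
same trajectories later in life. A synthetic-study generator plants all of
this structure with known truth so every stage is testable.

# The statistical model, stage by stage

## Detection diversity and its link to mortality

A feature's detected count in a sample is `sum(intensity > 0)`; the total
signal is the column sum. Counts are fitted with an ordinary least-squares
cubic *through all replicate points* (not replicate means), and the plateau
age is the smallest root of the fitted derivative inside the observed age
range at which the curvature is negative. Reading the plateau off the fit
rather than the raw argmax makes the estimate robust to replicate noise;
when the fitted trend is still rising at the last sampled age the function
returns `NA`, which genuinely happens for the long-lived diet — its
leveling-off is pushed towards the end of the sampling window.

Whether diversity changes with age at all is tested with the same
repeated-measures ANOVA used for the per-feature screen, applied to the
counts (age as the within factor, the replicate collection series as the
subject).

Survival utilities complete the picture: mean lifespan of fully observed
cohorts, per-interval death counts from a survivorship curve, and the
standard 1-df log-rank test (delegated to `survival::survdiff()`).

## The per-feature screen

For one diet, a feature detected in all 21 samples (7 ages x 3 replicates)
is *eligible*; a feature with any zero is routed to the diversity analysis
instead of being imputed — censored values carry information about
detection, not about levels. Eligible features are tested on the log10
scale with the one-way within-subject decomposition

$$SS_{total} = SS_{age} + SS_{subject} + SS_{residual},\qquad
  F = \frac{SS_{age}/(a-1)}{SS_{residual}/((a-1)(s-1))}$$

with `a` ages and `s` replicate series, no sphericity correction. Exact
fits ($SS_{residual}=0$ with a nonzero age effect) return an infinite-F
sentinel with p = 0; constant features return F = 0, p = 1. Significance
defaults to p < 0.0014 for metabolite matrices (p < 0.0013 is the
transcript-matrix convention; the code path is identical).

Two calibration tools accompany the threshold. `calibrate_threshold()`
operationalizes picking the threshold at the transition between the linear
and the exponential rise of the error rate: over 100 log-spaced candidate
thresholds from $1/m$ to a 0.05 cap it computes
$\widehat{FDR}(\alpha) = \alpha m / \max(R(\alpha), 1)$ and returns the
knee, located as the grid point of maximum perpendicular distance to the
chord joining the curve's endpoints in log-log space. The knee rule, grid
and cap are exposed because the underlying idea is qualitative; on
signal-free input the cap is returned with a `no_signal` flag.
`plug_in_fdr()` is the conservative $\pi_0 = 1$ estimator
$\alpha m / \#\{p \le \alpha\}$, undefined (NA) when nothing is
discovered.

## Cross-diet trajectory structure

Features significant in both diets are the *overlapping* set. Their
replicate-averaged log10 trajectories are compared by per-feature Pearson
correlation; the concordance statistic is the median matched-pair
correlation, and its null distribution comes from re-pairing features at
random between the diets ($p = (1 + \#\{\text{null} \ge \text{obs}\}) /
(n_{perm}+1)$). The median is used because it is the summary the
distribution is reported by; an exhaustive enumeration over all pairings is
available for small sets. Fold changes are orientation-free ratios
(max/min across ages within a diet; larger/smaller lifespan-averaged mean
between diets) with a twofold flag on the inter-diet ratio.

Scaling comes in two modes with different purposes: `within_diet` z-scores
each feature per diet (shapes only — level differences between diets are
removed), `across_diets` z-scores the concatenated two-diet trajectory
(level differences survive as opposite-sign per-diet means). Sample-space
PCA on across-diet-scaled replicate data separates diets along a leading
component; on within-diet-scaled data the leading component orders samples
by age in both diets — the operational signature that overlapping features
follow the same age trajectories at diet-specific levels.

## Clusters, diet dependence, and the remodeling delay

Overlapping features are clustered on their across-diet-scaled concatenated
trajectories with complete-linkage agglomeration on Euclidean distances,
cut into exactly k = 12 groups. The cited cutting operation on a
hierarchical tree is what "12 k-means clusters from rect.hclust" actually
computes, so tree-cutting is the default semantics; a k-means mode exists
for comparison.

Each cluster is classified by testing its inter-diet difference age by age
at $\alpha = 0.05$: significant at every age = `progressive`, at some but
not all = `intermittent`, at none = `independent`. Two statistical choices
matter here and are deliberate:

* **The per-age test unit is the replicate, and the per-sample summary is
  the median over member features.** Testing replicates keeps sample-level
  technical variation (e.g. residual normalization noise common to all
  features of a sample) inside the error term, where it belongs; with
  feature-level units that shared component masquerades as evidence and
  inflates the false-flag rate severalfold. The median (rather than mean)
  summary tracks the cluster's consensus trajectory, so a minority of
  members that do not share the cluster's behaviour — unavoidable when a
  fixed k = 12 cut meets more latent classes than 12 — cannot flip the
  cluster's label. A trimmed across-feature test (`units = "feature"`) is
  exposed for users who prefer power over robustness.
* **Holm adjustment across the seven per-age tests within a cluster.**
  Seven unadjusted 5% tests flag roughly a third of truly diet-independent
  clusters at one age by chance; Holm keeps the per-cluster false-flag
  rate at the nominal level while leaving the large planted effects
  detectable. `p_adjust = "none"` restores the plain rule.

Classification granularity is ambiguous in the source analysis
(per-metabolite side bars vs per-cluster categories); both are exposed,
cluster-level is the default, and `dependence_frequencies()` reports
feature-weighted fractions either way.

Remodeling-delay curves label clusters increasing or decreasing by the sign
of their net change in the short-lived diet, z-score member features'
replicate-level values per diet, average them into one global trajectory
per diet and direction, and fit a quadratic through the replicate points
for display. The *delay metric* — the age at which each diet attains half
of the short-lived diet's total change — is computed from the linearly
interpolated per-age means rather than from the quadratic: a second-order
polynomial cannot represent a ramp that levels off, and the resulting
distortion biases the half-change age ratio by about 10% even on noiseless
input, which we verified by direct computation. The metric is reported for
all clusters of a direction, for diet-dependent clusters, and for
progressive clusters alone; the progressive scope is the cleanest view of a
pure time delay because persistent level offsets vanish under per-feature
scaling and no transient differences contaminate the mean curve.

# The synthetic study generator

`generator_config()` fixes the emulated design: 2 diets x 7 age groups
(days 3, 10, 25, 40, 50, 60, 63 — the published schedule names day 3, days
10–50 and "60–63 days" but never prints all seven, so the in-between values
are a documented assumption) x 3 replicates; 2000 features by default as a
desk-scale stand-in for the >15,000 analytes of a real run (scaling up is a
config change); 14% planted age-associated features; 62% of those
diet-independent; 76% below twofold between diets; intradiet amplitudes of
4–8 fold (0.6–0.9 log10 units); replicate noise sd 0.1 on the log10 scale;
detection limit 1 on the intensity scale; mean lifespans 50.8 d (standard)
and 64.4 d (defined).

Mechanically, intensities are $10^{\text{template} + \text{noise}}
\times (1 - 0.003\,t)$, then left-censored at the detection limit. The
linear biomass factor emulates the shrinking of aging flies and gives the
total signal its slight decline. Trajectory templates are linear ramps
from the first age to the plateau age (50 d standard), constant after;
mid-life reversals are tents over the same window; "damage" features start
below the detection limit and rise through it at a feature-specific onset
age. Age-associated and damage features draw low baselines (1.5–2.5 log10
above the limit) — the planted counterpart of the observation that the
age-gained compounds are low-abundance — while flat features span a wide
abundance range including a thin near-limit band whose stochastic
detection keeps null detection counts variable.

Choices worth flagging:

* **Onset ages follow a linearly tapering (triangular) density** on
  [first age, plateau age] rather than a uniform one. A uniform density
  makes the expected detection curve piecewise linear with a sharp corner,
  and the cubic-fit plateau estimator then lands 7–8 days late *by
  construction*; the tapering density produces the saturating
  rise-then-level-off shape the estimator (and the real data) presuppose,
  and the estimate recovers the planted 50 d within a few days. The
  defined diet's onsets are the standard onsets rescaled onto its longer
  pre-plateau window.
* **The remodeling delay is planted on diet-dependent features.** The
  long-lived diet's template is the short-lived template evaluated at
  $t \cdot (50.8/64.4)$ — an exact time compression. Applying that warp to
  *every* age-associated feature would contradict the existence of
  diet-independent features (any consistent per-age test would detect the
  mid-life gap the warp opens), so diet-independent features are exactly
  identical across diets, progressive features carry the warp plus a
  persistent log10 offset of 0.5–0.8 (above twofold), and intermittent
  features carry the warp plus a transient mid-life offset of 0.55–0.75
  active over roughly ages 17–41 — "differs at some but not all ages" made
  literal. Effect sizes are near-saturating relative to the 0.1 noise sd;
  they are chosen so the three classes are separable by a k = 12
  complete-linkage cut, which is the actual bottleneck at weaker effects.
* **The global-null configuration (`null_config()`) switches off every
  planted age effect** — no age-associated features, no detection onsets,
  and also no biomass decline, since a body-mass trend is itself an age
  effect that would leak into every feature after normalization. Near-limit
  flat features are retained so detection counts still vary.
* Survivorship is Gompertz ($h(t) = a e^{bt}$) with b fixed at 0.1/day and
  only the baseline hazard calibrated, because a single printed mean
  lifespan is one constraint; the calibration solves for the integrated
  mean within 0.05 d and cohorts are sampled by inverse-CDF draws.
* Replicate noise is i.i.d. log-normal; there are no batch effects, no
  retention-time structure, no adducts or isotopes, and internal standards
  are three spiked constant features with 0.02 technical noise. Passing
  recovery tests on these data therefore demonstrates that the *machinery*
  is correct and calibrated — not that real LC-MS data satisfy the
  assumptions.

# Normalization

Raw tables are normalized per sample by the mean of the internal-standard
intensities and then by the post-standard total signal, in that order. The
source protocol names both normalizations without an order or combination
rule; standard-then-total is the package's choice (config-exposed), and
multiple standards enter through their per-sample mean. Zeros are preserved
exactly: normalization can never create or destroy a detection. Detection
counting is scale-invariant, so the diversity stage runs on raw tables;
the screen and everything downstream run on normalized ones.

# Numerical conventions and degenerate inputs

* Missing cells in input files are errors — the detection semantics demand
  explicit zeros; negatives and duplicate ids are rejected.
* Constant trajectories are excluded (with flags) from scaling and from
  correlations rather than producing NaN.
* Column sums after total-signal normalization are 1 within 1e-12; z-score
  rows have mean 0 and unit sample variance (n−1 denominator) within
  1e-12; scaling is idempotent at the same tolerance.
* Ties in the hierarchical tree are resolved by `stats::hclust`'s
  deterministic order, so clustering is reproducible given input order;
  PCA component signs are fixed by making each component's first nonzero
  loading positive.
* The permutation p-value uses the add-one convention and can never be 0;
  with `exact = TRUE` all pairings (including the identity) are enumerated.
* All seeded functions restore the caller's RNG state.

# Problem sizes used by the test suite

The suite validates calibration and recovery at sizes chosen to make the
statistical properties visible: five 20,000-feature global-null studies for
the false-positive rate of the screen (expected 0.14% at p < 0.0014, bound
0.2%); twenty 2,000-feature default studies for recovery of the planted
plateau (±7 d), diet-independent fraction (0.62 ± 0.06), below-twofold
fraction (0.76 ± 0.05) and delay factor (50.8/64.4 ± 10%); 200 small
re-pairing nulls for permutation super-uniformity; and 1,000-feature nulls
pooled over five seeds for Kolmogorov–Smirnov uniformity of the screen's
p-values. Single-cluster false flags at the classification stage occur at
the ~5% family-wise rate the α = 0.05 design implies, which is why the
recovery statements are about means over seeds rather than every seed.

# Known limitations

* The per-feature screen tests age as a categorical factor; no smoothness
  or monotonicity is modeled (no splines, no autoregression), matching the
  source analysis but discarding power against ordered alternatives.
* Censored values are never imputed into trajectories; features that cross
  the detection limit contribute to the diversity analysis only.
* The diet-dependence classifier inherits the arbitrariness of a fixed
  k = 12 cut: latent classes that the cut merges are classified by their
  consensus, and minority members are counted with their cluster.
* Gompertz survivorship with fixed b is a stand-in for unpublished cohort
  data; only the mean lifespan is calibrated, not the curve's shape.
* The generator's independence assumptions (no batch effects, independent
  features) make the null calibration results best-case; correlated real
  data would widen the screen's error bars.
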