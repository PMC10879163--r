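---
title: "Discovering projection-neuron classes from brain-wide axonal reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering projection-neuron classes from brain-wide axonal reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoclass)
```

## The classification problem

A source region projecting to $k$ target parcels could in principle house any
of $2^k - 1$ distinct axonal projection types. Given brain-wide single-axon
reconstructions registered to a common atlas, each neuron is summarized as a
$k$-dimensional vector whose components count the axonal tracing points in
each target parcel. The question `axoclass` answers is statistical, not
descriptive: do the observed projection vectors reflect genuinely distinct
neuron classes, or merely random variation within the constraints of the
region's overall connectivity?

The method couples three ingredients:

1. **A marginal-preserving null.** The single-class hypothesis is embodied by
   the ensemble of count matrices sharing the data's row sums (per-neuron
   axonal extent) and column sums (per-region targeting). `randomize_matrix()`
   samples it by repeated pairwise swaps: two neurons, two regions, an amount
   $\delta$ moved diagonally, which conserves both margins exactly and keeps
   counts non-negative integers.
2. **Arccosine projection distances.** `arccos_distance()` measures the angle
   between two count vectors in degrees: 0 for proportional targeting, 90 for
   disjoint targeting. The angle ignores total axonal size (scale
   invariance), so it isolates the *pattern* of targeting.
3. **A one-tailed Levene gate.** If distinct classes exist, pairwise angles
   mix small within-class and large between-class values, widening their
   distribution relative to the null. `levene_one_tailed()` runs the
   absolute-deviation Levene test (a one-way ANOVA on $|x - \bar x_g|$)
   comparing experimental against randomized distances, and is directional:
   only a significantly *larger* experimental variance justifies splitting.
   When the variance points the other way the p-value is reported as not
   applicable and the recursion stops.

`discover_classes()` wires these into recursive average-linkage (UPGMA)
clustering: the whole cohort is tested against a fresh randomization; on a
positive answer the dendrogram's top bipartition defines two subtrees, each
re-tested on its own submatrix with its own fresh null. Terminal nodes are
the classes, labeled `A`, `B`, ... in dendrogram order with sizes appended.

## Why point counts rather than cable length

Light-microscopy tracings cannot distinguish synapse-bearing arbor from
fibers of passage, and the longest unbranched stretches are typically
passage. Tracers place points more densely where the arbor meanders through
synaptic neuropil, so the *number* of tracing points per region is a better
proxy for connective extent than summed length. `metric_justification_report()`
quantifies this on any cohort: the correlation between branch point count
and branch length, and the contrast in branch length and point spacing
between Strahler orders 1–3 (terminal side, synapse-rich) and 4–6 (mostly
passage), with one-tailed Welch t-tests on per-neuron band means. The
per-neuron (rather than per-branch) unit was chosen because branch counts
run into the tens of thousands while the field's reported degrees of freedom
for these contrasts are two orders of magnitude smaller, which is consistent
with neuron-level aggregation; this is recorded as an approximation.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | significance level of each Levene split decision |
| `min_subtree` | 3 | smallest subtree still tested; 2 neurons give a single pairwise distance, so a variance test is impossible |
| `n_swaps` | 20 × nonzero cells | successful swaps per randomization |
| `delta_rule` | `"uniform"` | δ drawn uniformly from `1..min(M[i,a], M[j,b])`; `"max"` moves the feasible maximum |
| `midline` | 5695 µm | mediolateral midline coordinate deciding ipsi/contra |
| hull `min_points` | 4 | minimum somata for a convex hull |

The swap count and δ rule are not prescribed by the procedure itself, only
"multiple iterations" of swapping; 20× the nonzero cells gives the chain
ample time to decorrelate on cohort-sized matrices (a few thousand cells),
and the uniform δ mixes faster than single-unit moves. Both are exposed in
`swap_config()` for sensitivity analysis. Each subtree receives a fresh
randomization of its own submatrix rather than a slice of the root null, so
every test conditions on its own marginals.

## Numerical choices

* Angles are computed in degrees; the cosine is clamped to $[-1, 1]$ before
  `acos` to absorb rounding.
* UPGMA ties (minimum inter-cluster distances within $10^{-12}$) are broken
  lowest-index-first, making the dendrogram — and hence the class labels —
  fully deterministic.
* Zero-count neurons have no projection direction; they are kept in the
  matrix (their marginals matter to the null) but excluded from distances
  and reported as unclassified.
* In the Levene statistic a zero within-group sum of squares is resolved by
  the limit: F = ∞, p = 0 if the between-group term is positive, else F = 0,
  p = 1.
* The 3D convex hull is built incrementally (beneath–beyond) with an
  epsilon of $10^{-9}$ times the coordinate range; the exact intersection
  volume of two hulls is the hull volume of the candidate vertices (vertices
  of either hull inside the other plus edge–boundary clip points), with a
  seeded Monte-Carlo estimator as a cross-check and fallback.
* Soma outlier pruning follows the leave-one-out 1/n rule in a single pass
  over all points against the original hull: flags are simultaneous (so the
  result is input-order independent), and if pruning would leave fewer than
  four somata, all points are retained.

## Population fractions by NNLS

Single-neuron counts say nothing about how *many* neurons of each class the
source region contains, because reconstruction sampling is not proportional
to abundance. Regional anterograde tracing profiles (projection volume ×
density per target region, averaged over experiments and normalized —
`build_b()`) constrain the mixture: with class signatures assembled from
summed per-class counts and bi-normalized (`binormalize_A()`: rows to 1,
grand total to $k$, columns to 1), non-negative least squares recovers the
fraction vector $x \ge 0$ minimizing $\lVert Ax - b\rVert$. The residual is
reported both raw and as a percentage of $\lVert b\rVert^2$, since either
convention may be wanted when judging fit quality. `afferent_composition()`
then apportions each target's afferents across classes by fraction × mean
per-neuron count (the mean, not the sum, so class size does not enter
twice).

## What the synthetic generators emulate — and what they do not

`generate_cohort()` draws each neuron's total from a log-normal (default
median 2000 points, σ = 0.7 — the scale of whole-brain single-axon
tracings) and distributes it multinomially by a class profile. This captures
the count structure the statistics consume, but deliberately omits spatial
autocorrelation along the arbor, registration error, and tracing
idiosyncrasies of real data. `presubiculum_like_classes()` plants five
classes with the population sizes (38, 27, 3, 19, 6) and dominant-target
compositions observed for presubicular projection neurons.
`generate_tree()` grows random binary arbors with controllable
length/spacing contrast between Strahler bands (defaults 150 vs 950 µm and
20 vs 40 µm), and `generate_soma_clusters()` places Gaussian soma blobs at
controlled separations. All generators are pure functions of (spec, seed).

Passing tests on these cohorts therefore show that the machinery is correct
and that the procedure recovers planted structure under idealized count
statistics; they do not certify behavior under the artifacts of real
tracing data.

## Calibration of the split decision

Two properties of the gate deserve explicit mention, both established by
simulation in the test suite:

* Against cohorts drawn from a *single multinomial profile*, the test is
  strongly conservative: the swap ensemble is close to uniform on the
  marginal fiber, which is overdispersed relative to multinomial sampling,
  so the randomized distances almost always have the larger variance and
  the one-tailed gate never fires (0 splits in 500 runs at α = 0.05). A
  single planted class is thus essentially never fragmented.
* The pairwise distances entering the Levene test are correlated (all pairs
  share neurons), so its nominal p-values should be read as a gating
  heuristic rather than exact error rates; the directional rule and the
  per-subtree fresh null are what keep the recursion honest in practice.

## Problem sizes

The shipped tests and the acceptance script run cohorts of 40–135 neurons
over 7–12 regions, 500-run calibration sweeps, $10^5$-swap conservation
checks, and 100-tree path-distance oracles; these sizes were chosen so the
statistical claims are sharp while a full run stays comfortable on a
laptop-class single core.

## Known limitations

* Per-point parcel annotation is taken as input; no atlas registration is
  performed.
* Hemisphere assignment uses a single sagittal midline coordinate, adequate
  for atlas-registered data but not for unregistered coordinates.
* The Levene gate tests variance only; classes differing in mean distance
  but not variance structure would require a different gate.
* The exact hull intersection assumes generic position; severely degenerate
  contacts (shared faces) fall back to the Monte-Carlo path.
* The rank tests on path distances pool per-point values, matching how
  sample sizes are reported in this literature; points from one neuron are
  not independent, so the per-neuron-median variant is also reported.
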