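# axoclass

Statistical discovery of projection-neuron classes from brain-wide
single-axon reconstructions.

## The problem

Whole-brain tracing projects (MouseLight, fMOST) now provide thousands of
complete single-axon reconstructions registered to a common atlas. A source
region projecting to *k* target parcels could contain any of 2^k − 1
projection types, so the first scientific question is whether statistically
distinct classes exist at all — as opposed to axons invading a random subset
of the region's targets. `axoclass` is for anatomists and neuroinformaticians
who want that question answered with an explicit null model rather than by
eyeballing a dendrogram.

## The method

Each neuron is a count vector: axonal tracing points per (parcel,
hemisphere) column. Point counts, not cable length, measure axonal extent —
tracing density is higher in synapse-bearing neuropil than along fibers of
passage, which `metric_justification_report()` verifies on any cohort via
Strahler-order branch statistics.

The single-class null hypothesis H₀ is the ensemble of count matrices with
the data's row sums (axonal sizes) and column sums (regional targeting),
sampled by stochastic pairwise swapping of counts between two neurons
across two regions. Pairwise neuron differences are arccosine vector
angles, arccos(u·v / ‖u‖‖v‖), in degrees. If classes exist, the observed
angles mix small within-class and large between-class values, so their
variance exceeds the null's: a one-tailed absolute-deviation Levene test
(one-way ANOVA on |x − x̄_g|) gates each split of an average-linkage
dendrogram, recursing with a fresh null per subtree until no significant
variance excess remains. Terminal nodes are the classes (`A38`, `B27`, ...).

Downstream modules quantify the discovered classes: class population
fractions by non-negative least squares against regional anterograde
tracing profiles (min ‖Ax − b‖, x ≥ 0, with bi-normalized signatures);
soma topography by convex-hull volumes, the leave-one-out 1/n outlier
rule, and exact intersection/union overlap ratios; and soma-to-target
path-distance divergence/convergence via rank-sum tests with
Benjamini-Hochberg correction.

## Worked example

```r
library(axoclass)

# a presubiculum-like cohort: 5 planted classes, sizes 38/27/3/19/6,
# ~2000 axonal points per neuron over 12 target groups
cohort <- generate_cohort(presubiculum_like_classes(), seed = 42)
cohort$matrix
#> <projection_matrix> 93 neurons x 12 columns, total 237733 axonal points

tree <- discover_classes(cohort$matrix, seed = 43)
tree
#> <class_tree> 4 classes over 93 neurons: A6, B19, C38, D30

tree$node_tests$root
#> <levene_result> F = 3244 on (1, 8554) df; one-tailed p = 0;
#>   var exp = 1553, var rnd = 510.4 -> split
```

The root test rejects the single-class null decisively (experimental
variance 1553 deg² versus 510 deg² under randomization), and recursion
recovers the planted structure: the thalamic class (6 neurons), the
subiculum/hypothalamus/midbrain class (19), and the entorhinal class (38)
come out exactly; the 3-neuron contralateral class is merged with its
27-neuron neighbor (D30) at this seed — with only three members and a
partially overlapping profile its variance signal is below the gate, the
same abstention the method is designed to make rather than over-split.

Reading real data instead:

```r
neurons <- parse_projection_json("AA0001.json")   # MouseLight-style JSON
# or: parse_swc("AA0001.swc")
M <- build_projection_matrix(neurons, hemisphere_split = TRUE)
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/axoclass.R simulate --seed 1 --out sim
Rscript inst/cli/axoclass.R classify --matrix sim/matrix.csv --seed 2
Rscript inst/cli/axoclass.R run --in reconstructions/ --out results/
```

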