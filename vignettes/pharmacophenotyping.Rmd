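---
title: "Two-level pharmacophenotyping of ICU medication records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level pharmacophenotyping of ICU medication records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmphen)
```

## The analysis

Critically ill patients receive complex medication regimens, and the full
medication administration record (MAR) of the first 24 hours of an ICU stay
carries information about both the patient's condition and the care they are
receiving. `pharmphen` implements a two-level unsupervised analysis of such
records:

1. **Medication level.** Each distinct drug order is a binary exposure
   variable; a restricted Boltzmann machine (RBM) trained on the
   patient-by-order exposure matrix groups co-occurring orders into
   *pharmacophenotypes*, with an explicit bucket for orders that activate no
   hidden unit.
2. **Patient level.** Each patient is summarized by their normalized
   distribution over pharmacophenotypes, and patients are grouped by
   hierarchical agglomerative clustering (HAC) of those distributions.
   Patient clusters are then compared pairwise on clinical outcomes with
   nonparametric tests under Holm familywise adjustment.

The package also ships a synthetic MAR generator with planted structure, so
that the whole pipeline can be exercised and validated without access to
protected health data.

## Order keys and the exposure matrix

A drug order is identified by the composite of drug, dose, strength,
formulation and route. `build_order_key()` canonicalizes these free-text
fields (case folding, whitespace collapsing) and joins them with `|`; two
orders differing in any component — e.g. two dose levels of the same
antibiotic — are distinct keys, because their clinical meaning differs.
`encode_matrix()` then builds the binary cohort matrix: entry `(i, m)` is 1
iff patient `i` received order `m` at least once in the window. Duplicate
administrations collapse; unknown or missing entries count as absences.
Columns are ordered lexicographically by key so that every downstream model
sees the same matrix regardless of input row order.

## Dimensionality reduction

`fit_pca()` performs PCA (SVD of the centered matrix; binary indicators
share a scale, so no per-column scaling) and keeps the smallest number of
components whose cumulative explained-variance ratio exceeds the target
(default 0.70), optionally capped (default 150, the cap appropriate at the
scale of several hundred order keys). Component signs are fixed by making
each component's largest-magnitude loading positive, so results are
run-stable. In this pipeline PCA serves as a diagnostic/auxiliary branch:
the patient clustering default operates on phenotype distributions (below),
with `cluster_features = "pca"` available to cluster PCA scores of the
exposure matrix instead — the two readings of the original workflow.

## The restricted Boltzmann machine

The RBM is a two-layer energy-based model over binary visible units `v` (the
medication exposures) and binary hidden units `h` (the phenotypes), with

$$E(v, h) = -b^\top v - c^\top h - h^\top W v,\qquad
  p(v, h) \propto e^{-E(v, h)}.$$

Conditionals factorize: $p(h_j = 1 \mid v) = \sigma(c_j + W_{j\cdot} v)$ and
$p(v_m = 1 \mid h) = \sigma(b_m + W_{\cdot m}^\top h)$. `train_rbm()`
maximizes the likelihood approximately by contrastive divergence (CD-k):
the positive phase uses data-clamped hidden probabilities, the negative
phase runs `k` alternating Gibbs steps (sampled hidden and visible states,
with the final hidden term taken as probabilities), and the update follows
$\langle v h^\top\rangle_\text{data} - \langle v h^\top\rangle_\text{model}$.

Defaults: `K = 5` hidden units, `5000` epochs, learning rate `0.05`,
minibatch `32`, CD-1, weights initialized `Normal(0, 0.01)`, biases zero.
These are conventional CD settings; all are exposed as arguments and
recorded on the fitted object. Training is driven entirely by one integer
seed. Divergence (non-finite parameters) aborts with the epoch named.

Training progress is monitored by a deterministic **full-coordinate
pseudo-log-likelihood** (`pseudo_log_likelihood()`): for each observation
and each coordinate, the model's conditional log-probability of the observed
bit given the rest, $\log\sigma(F(\tilde v_m) - F(v))$, where $F$ is the free
energy and $\tilde v_m$ flips bit `m`. It is exact (no coordinate
sampling), so traces are reproducible and comparable across runs. For small
models `rbm_exact_gradient()` computes the exact likelihood gradient by
enumerating all visible states — the oracle against which the CD direction
is validated in the test suite.

## From hidden units to pharmacophenotype assignments

`assign_medications()` converts the trained model into a medication-to-
phenotype map. Medication `m` joins every phenotype `j` whose activation
probability exceeds a threshold `tau` (default 0.5, the natural decision
boundary of the logistic); a medication exceeding the threshold nowhere
falls into the explicit unassigned bucket `K + 1`. Multi-membership is
allowed — the membership sets are exactly the overlap structure between
phenotypes.

What counts as "activation" was a genuinely open design choice, and the
package implements both readings:

* **`probe = "data"` (default).** The activation of unit `j` for medication
  `m` is the mean of $p(h_j = 1 \mid v)$ over the training patients exposed
  to `m` — the activation pattern the unit actually exhibits for that
  medication in the cohort.
* **`probe = "onehot"`.** The activation is $\sigma(c_j + W_{jm})$, the
  hidden response to the medication's one-hot visible vector in isolation.

The data-conditional rule is the default for a substantive reason: CD-trained
RBMs routinely learn *distributed* codes, in which a block of co-occurring
medications is represented by a combination of hidden units rather than a
single dedicated unit. On realistic visible configurations those codes are
fully expressed and are consistent across a block; a one-hot input, by
contrast, under-drives the hidden layer and can split a coherent block
across phenotypes. In the package's planted-structure recovery tests the
data probe recovers the planted medication groups (as equivalence classes of
identical membership patterns, see `assignment_patterns()`), while one-hot
probing does not reach the same fidelity under any conventional CD
hyperparameter setting we examined. Because multi-membership sets rather
than single labels are the assignment, recovery is scored on the partition
the patterns induce; `primary_phenotype()` provides the argmax reduction
when a single label per medication is required.

## Phenotype distributions and patient clustering

`phenotype_distribution()` turns the matrix and assignment into each
patient's normalized phenotype frequency vector over phenotypes
`1 .. K + 1`. In `"fractional"` mode (default) a key belonging to several
phenotypes splits its unit mass equally, making every row a probability
vector — simplex-valued features are well suited to Euclidean clustering.
`"full"` mode credits each member phenotype fully (rows can sum to more
than 1), matching a literal per-phenotype counting convention.

`hac()` clusters the distributions bottom-up. Linkage defaults to Ward on
Euclidean distances (the common default of the toolkit ecosystem this
analysis pattern comes from); average, complete and single linkage are
available, all via the Lance–Williams recurrence as implemented in
`stats::hclust()` (Ward in the `ward.D2` convention, i.e. heights on the
distance scale). `cut_tree()` yields labels renumbered by descending
cluster size with a lowest-index tie-break, so label identities are stable
across runs. `suggest_k()` is the programmatic surrogate for visual
dendrogram inspection: it maximizes the relative merge-height gap
$(h_{\text{above}} - h_{\text{below}}) / h_{\text{below}}$ over candidate
cluster counts and returns the full gap table so the choice can be
overridden by eye; a flat tree (all heights equal) falls back to `k = 2`
with a warning.

## Outcome comparisons

`pairwise_compare()` tests every unordered pair of patient clusters against
every outcome: Mann–Whitney rank-sum tests (midranks for ties; exact
enumeration when the pooled sample is at most 12 and tie-free, otherwise
the tie-corrected normal approximation with continuity correction) for
continuous outcomes, and Fisher's exact test (two-sided by the
point-probability rule) for categorical outcomes. Cluster comparisons are
between independent groups, so the rank-sum test is used throughout; the
paired signed-rank test is exposed separately (`signed_rank_test()`) for
paired designs. Missing outcome values are excluded pairwise with
per-outcome denominators. Holm's step-down adjustment is applied within
each outcome family across its cluster pairs (10 pairs at 5 clusters),
controlling the familywise error rate per outcome at the configured level
(default 0.05); both raw and adjusted p-values are reported, since summary
tables in this literature are ambiguous about which is printed.

`cluster_summary()` builds the per-cluster descriptive table (mean ± SD;
event counts with explicit denominators) and appends the pooled column via
`pooled_summary()` — pooled means are size-weighted means of cluster means,
pooled percentages use summed counts over summed denominators, and both are
rounded to one decimal for reporting. `phenotype_profile()` cross-tabulates
phenotype membership against medication annotations (drug class, route
flags), counting unannotated keys explicitly. `radar_table()` produces the
per-cluster mean phenotype distribution behind the radar-chart view of the
results.

The package ships, as plain CSV, the per-cluster summary cells of the
published 991-patient reference cohort (`reference_cohort_summary()`);
feeding them to `pooled_summary()` reproduces that report's pooled column by
arithmetic alone — the only part of the original study that is reproducible
without its (undeposited) patient-level data.

## The synthetic cohort generator

`synthetic_spec()` + `generate_cohort()` define the test bed. The generative
model mirrors the statistical structure the analysis assumes, nothing more:

* medications are partitioned into `n_groups` planted groups (round-robin,
  sizes within one of each other);
* each patient draws an archetype uniformly; an archetype is a mixing
  distribution over groups (default: 0.8 on the diagonal, the rest spread
  evenly — strong but not deterministic group preference);
* order counts are `max(1, Poisson(20))`: every admitted patient has a
  nonempty regimen, and 20 orders against a 100-medication formulary keeps
  the orders-to-formulary ratio of a realistic first-24-h MAR extract;
* each order picks a group from the mixing row, a medication uniformly
  within the group, and is replaced by a uniformly random medication with
  probability `noise_rate` (default 0.05);
* continuous outcomes are Normal with archetype-specific means (severity
  scores, lengths of stay, support durations at ICU-typical values);
  categorical outcomes are Bernoulli with archetype-specific probabilities
  (mortality, AKI, ventilation). `null_outcome_effects()` equalizes all
  archetypes for type-I-error studies.

Draws are organized as one master seed plus deterministically derived
per-patient and per-outcome sub-seeds, so cohorts are bytewise reproducible
and any single patient's records can be regenerated in isolation.

What the generator does **not** emulate: realistic pharmacology (doses,
interactions, PK/PD), time-resolved administration dynamics beyond a
timestamp, correlated outcome structure, or the long-tailed order-frequency
distribution of real formularies. Passing recovery tests therefore shows
that the pipeline recovers the kind of co-occurrence structure it assumes —
not that real MAR data contains such structure.

## Validation design and problem sizes

The test suite validates every computational step against an independent
oracle: exhaustive joint-state enumeration for the RBM gradient, an
eigendecomposition for PCA scores, a naive all-pairs recomputation for each
HAC linkage, full combinatorial enumeration for the rank-sum and Fisher
tests, the textbook step-down for Holm, and brute-force counting for
distributions and profiles. Planted-structure recovery uses the standard
synthetic cohort (500 patients, 100 medications, 5 groups, 5 archetypes,
diagonal mixing 0.8, noise 0.05) over 5 seeds, with recovery summarized by
the median adjusted Rand index; familywise type-I control uses 200 null
replicates of 500 patients. These sizes keep the full suite comfortably
within a few minutes on one CPU while leaving the recovery margins wide.

## Limitations

* The RBM has limited expressiveness; strongly overlapping or hierarchical
  medication patterns may not separate into distinct phenotypes, and hidden
  codes are distributed rather than one-unit-per-group (addressed by the
  pattern-based assignment, but a fundamental property of the model).
* Cluster–outcome associations are descriptive; nothing in the pipeline
  supports causal interpretation.
* The gap heuristic in `suggest_k()` is a surrogate for expert inspection
  and can be misled by chained or unbalanced dendrograms; the gap table is
  returned precisely so a human can overrule it.
* Real regimen-complexity weight tables are not distributed with the
  package; `regimen_complexity()` accepts a user-supplied weight table.
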