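# pharmphen

Two-level unsupervised **pharmacophenotyping** of ICU medication
administration records (MAR), for critical-care researchers and
pharmaco-epidemiologists who want to find structure in *what was actually
administered* during the first day of an ICU stay.

The pipeline:

1. **Encode.** Every drug order is canonicalized into a composite key
   (`drug|dose|strength|formulation|route`) and the cohort becomes a binary
   patient × order-key exposure matrix `X` (`X[i, m] = 1` iff patient `i`
   received order `m`; duplicates collapse, missing counts as absence).
2. **Learn pharmacophenotypes.** A Bernoulli restricted Boltzmann machine
   with energy `E(v, h) = -bᵀv - cᵀh - hᵀWv` is trained on `X` by
   contrastive divergence (CD-k). Each medication joins every hidden unit
   (pharmacophenotype) whose activation probability for that medication
   exceeds a threshold τ (default 0.5); medications activating no unit form
   the explicit unassigned phenotype `K + 1`. Membership may overlap.
3. **Cluster patients.** Each patient is reduced to their normalized
   phenotype distribution (a probability vector over `K + 1` phenotypes),
   and patients are grouped by hierarchical agglomerative clustering (Ward
   linkage by default) with a merge-gap heuristic standing in for visual
   dendrogram inspection.
4. **Compare outcomes.** All cluster pairs are tested on each clinical
   outcome — Mann–Whitney rank-sum for continuous, Fisher's exact for
   categorical — with Holm step-down adjustment within each outcome family.

A synthetic cohort generator with planted medication groups, patient
archetypes and archetype-dependent outcomes makes every stage testable
without any protected health data; the per-cluster summary cells of the
published 991-patient reference cohort are shipped as plain CSV so its
pooled demographics table can be reproduced by arithmetic.

## Worked example

```r
library(pharmphen)

spec   <- synthetic_spec(n_patients = 200, n_medications = 60, n_groups = 5,
                         n_archetypes = 5, seed = 42)
cohort <- generate_cohort(spec)
#> <synthetic_cohort> 200 patients, 3973 orders, 60 medications

exposure <- encode_matrix(cohort$mar)
#> <cohort_matrix> 200 patients x 60 order keys, density 0.214

rbm <- train_rbm(exposure, K = 5, epochs = 1500, seed = 42)
#> <rbm_model> 5 hidden x 60 visible units; 1500 epochs (CD-1), final PLL -20.978

assignment <- assign_medications(rbm, exposure)
dplyr::count(assignment_patterns(assignment), pattern)
#> # A tibble: 5 × 2
#>   pattern     n
#> 1 1          12
#> 2 1+2+4      12
#> 3 1+3+4+5    12
#> 4 2+4+5      12
#> 5 4          12
```

The 60 medications fall into exactly five membership patterns of 12
medications each — the five planted co-occurrence groups, recovered as
distinct (overlapping) phenotype signatures.

```r
dist <- phenotype_distribution(exposure, assignment)
tree <- hac(dplyr::select(dist, -total_orders))
suggest_k(tree)$k
#> [1] 5

labels <- cut_tree(tree, 5)
cmp <- pairwise_compare(labels, cohort$outcomes,
                        c(apache_ii = "continuous", mortality = "categorical"))
head(dplyr::arrange(cmp, p_holm), 3)
#>   outcome   test     cluster_a cluster_b   n_a   n_b statistic  p_raw p_holm
#> 1 apache_ii rank_sum         3         5    37    35       853 0.0209  0.209
#> 2 apache_ii rank_sum         2         3    46    37       630 0.0434  0.390
#> 3 apache_ii rank_sum         1         5    47    35      1025 0.0583  0.466

mclust::adjustedRandIndex(
  dplyr::inner_join(labels, cohort$truth_archetypes, by = "patient_id")$cluster,
  dplyr::inner_join(labels, cohort$truth_archetypes, by = "patient_id")$archetype)
#> [1] 0.939
```

The dendrogram gap picks the planted five archetypes, the cut recovers them
(adjusted Rand index 0.94 on this run), and the comparison table reports
raw and Holm-adjusted p-values per cluster pair and outcome — here no pair
survives adjustment, as expected at these modest planted severity shifts.

`run_pipeline(pipeline_config(...), output_dir)` executes the whole
workflow (simulate/load → encode → PCA → RBM → assign → distribute →
cluster → compare → report) and writes every stage table (exposure matrix,
model JSON, assignments, distributions, linkage, labels, comparisons,
per-cluster + pooled summary, per-cluster mean phenotype distributions)
plus the effective configuration; identical configuration and seed yield
byte-identical outputs.

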