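---
title: "Subnetwork biomarker discovery: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subnetwork biomarker discovery: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnetmark)
```

# The problem

Single-gene expression markers are noisy and travel poorly between cohorts.
A common remedy in cancer transcriptomics is to aggregate expression over
*subnetworks*: connected sets of genes in a protein–protein interaction
(PPI) graph whose joint dysregulation discriminates tumor from normal
tissue. `subnetmark` implements one such workflow end to end: partition a
STRING-style interaction network into candidate subnetworks, rank the
candidates by how well their most differentially expressed genes separate
sample classes, summarise each subnetwork per sample as a metagene
*activity score*, test activities for tumor/normal differences, classify
samples from activity features, and stratify patient survival by composite
activity.

The pipeline is exercised and validated entirely on a synthetic
planted-module test-bed, so every stage is testable without any data
download.

# Stage-by-stage model

## Network partitioning

Candidates come from recursive spectral bisection of the interaction
graph: any connected component larger than `max_size` (default 50) is
split by the sign of its Fiedler vector — the eigenvector of the
second-smallest eigenvalue of the confidence-weighted graph Laplacian
(STRING scores scaled to [0, 1]) — and the procedure recurses until every
cluster is small enough. Clusters below `min_size` (default 8) are
absorbed into the neighbouring cluster sharing the most edges. Optionally
each cluster then annexes 1-hop neighbours that have strictly more than
half of their edges inside it; this *boundary expansion* is the only
mechanism by which candidates can overlap, and therefore the only thing
that makes the later merge step non-vacuous.

Divisive spectral bisection was chosen because it is non-greedy in the
agglomerative sense, deterministic up to documented sign conventions
(Fiedler entries that are exactly zero go to the positive side; the
eigenvector sign is fixed by making its first nonzero entry positive, with
vertices processed in sorted-name order), and auditable through a simple
quality metric, the cut *conductance*. The size band 8–50 brackets
subnetworks of a few tens of genes, the scale at which PPI modules are
usually interpreted; both bounds are configurable.

## Representative genes and the entropy score

Within each candidate, per-gene differential expression is measured by an
IQR-modified Welch statistic

$$t_{\mathrm{IQR}} = \frac{\tilde{x}_T - \tilde{x}_N}
  {\sqrt{s_T^2/n_T + s_N^2/n_N}}, \qquad s = \mathrm{IQR}/1.349,$$

with medians in place of means and the Gaussian-consistent robust scale
IQR/1.349 in place of the standard deviation. Quartiles use
linear-interpolation quantiles (type 7); the convention matters because
IQR values differ across quantile definitions, so it is fixed and
documented. Genes whose IQR is zero in both groups get an undefined
statistic and are excluded rather than assigned an infinite one. A plain
Welch variant is available behind `statistic = "welch"` for sensitivity
analysis.

The five largest-|t| genes (ties broken by gene id) are the subnetwork's
*representatives*. Samples are clustered on the standardized
representative expression by k-means with k equal to the number of classes
and a deterministic initialization (the two samples at maximum city-block
distance seed the centroids; Lloyd iterations to a 1e-8 tolerance). The
subnetwork's score is the weighted mean class entropy over clusters,

$$H = \sum_c \frac{n_c}{N}\Big(-\sum_k p_{ck}\log_2 p_{ck}\Big),$$

zero when every cluster is class-pure and 1 bit at worst for two classes.
Lower is better. Candidates whose gene sets overlap with Jaccard index at
least 0.5 are merged (union of genes, everything rescored) and the final
list is ranked by entropy, ties broken by conductance then id. The 0.5
threshold operationalises "significant overlap"; it is configurable.

k-means with a deterministic seed was selected over hierarchical
clustering for reproducibility and because the entropy score only consumes
the induced partition; with all samples identical the clustering is
degenerate and flagged rather than fabricated.

## Activity scores and significance

The activity of subnetwork $S$ in sample $j$ is

$$a_j = \frac{1}{|U|}\sum_{g \in U} x_{gj} - \frac{1}{|D|}\sum_{g \in D} x_{gj},$$

the mean expression of its up-regulated genes minus the mean of its
down-regulated genes (one-sided when a set is empty). By default $U$ and
$D$ contain *every* subnetwork gene with a finite statistic, oriented by
the sign of its training-set $t_{\mathrm{IQR}}$; the
`gene_scope = "representatives"` switch restricts to the five
representatives. The all-genes default is the plain reading of
"up-regulated and down-regulated genes" and averages more genes, which
stabilises the metagene; the restricted mode is kept for sensitivity
analysis. Directions are estimated on training data only and frozen
before any held-out data is scored — an explicit anti-leakage contract.

Each subnetwork's activity is compared between tumor and normal samples
with a classical Welch t-test (Satterthwaite degrees of freedom),
p-values are Benjamini–Hochberg adjusted across subnetworks, and
selection requires adjusted p strictly below `alpha` (default `1e-5`).

**A known limitation worth stating plainly:** when the significance test
runs on the same samples used to orient the gene directions, it is
circular. Under a global null the oriented activity difference is a mean
of folded normals — roughly $0.7\sigma$ for homoscedastic noise — so the
training-set Welch statistic is inflated (|t| of 4–11 across ~30
candidates is typical in our null simulations) and the family-wise false
discovery rate at adjusted p < 1e-5 is far above nominal. The package
implements the workflow as designed (directions and test both on the
training cohort) because that is the published design; the null behaviour
is characterised honestly by the test suite rather than patched with a
permutation calibration, which is out of scope. Interpretation of
training-set significance should keep this bias in mind; held-out
evaluation (the classifier transfer below) is unaffected.

## Classification

Samples are classified from subnetwork-activity features by k-nearest
neighbours with the city-block (Manhattan) distance and k = 5.
Generalisation is estimated by two-level nested cross-validation: 10
stratified outer folds; within each outer-training portion, 10 stratified
inner folds select k from {1, 3, 5, 7, 9} by inner accuracy (ties to the
smallest k); the model is refit on the outer-training portion and outer
test predictions are pooled into one confusion table, accuracy,
sensitivity, specificity and AUC. Because the workflow fixes k = 5 for the
final model yet also prescribes nested validation, the inner loop defaults
to grid selection with a `fix_k = TRUE` switch that freezes k = 5
throughout.

Design details: stratification is necessary at 34-vs-6 class imbalance;
vote ties (possible only with even k) break toward the positive class
(tumor), and the default grid is odd-only so they do not arise; distance
ties at the k-th neighbour break by training-sample id after a
deterministic sort, making predictions invariant to training-row order.
The AUC ranks samples by the KNN tumor-vote fraction, which with k = 5 is
a coarse 6-level score — a documented limitation of hard-voting KNN.
Anything data-dependent about the features (per-fold gene selection and
direction estimation) can be recomputed inside each outer fold via a
feature-builder callback, and the pipeline uses it, so no sample
influences its own prediction; the test suite verifies this with an
extreme-valued canary sample.

PCA of the activity matrix (centered, unscaled; component signs fixed by
making each component's largest-magnitude loading positive) provides the
unsupervised separation check.

## Survival stratification

A composite risk score per patient is the mean of z-standardized activity
scores over the selected subnetworks, each oriented so that higher means
more tumor-like (subnetworks with negative training Welch t are flipped).
Patients strictly above the median composite form the high-risk group
(ties at the median go low; the cut quantile is configurable). Survival
curves use the Kaplan–Meier product-limit estimator with the standard tie
convention (records censored at t remain at risk for events at t), group
differences use the two-group log-rank test (chi-square, 1 df, two-sided)
at significance threshold 0.05, and the analysis repeats within
estrogen-receptor strata when ER status is available. The median split and
mean-of-z composite are the least-parameter choices for turning several
subnetwork scores into one stratifier; both are documented rather than
claimed from any external source.

# The synthetic test-bed

`simulation_config()` defines the generative model the whole test suite
runs on:

* **Network** — Barabási–Albert preferential attachment on `n_genes`
  nodes (`attachment_m = 3` edges per node), matching the heavy-tailed
  degree structure of PPI networks. `n_planted_modules = 4` disjoint
  modules of `module_size = 20` genes receive additional intra-module
  edges with probability `module_extra_edge_prob = 0.8`, giving planted
  intra-module degrees (~15) well above the background mean (~6) — the
  regime of protein-complex-like dense communities. Below roughly the
  background degree the planted sets are not communities in any
  recoverable sense and no partitioning method could find them, so the
  dense default is what "densely connected planted modules" requires.
  All edges carry STRING-style confidence 999.
* **Expression** — gene baselines from Normal(7, 1) on the log2 scale,
  homoscedastic Normal(0, `noise_sd = 1`) noise, and a ±`effect_size_delta
  = 2` shift of planted genes in tumor samples only, with `frac_down =
  0.3` of each module shifted down (modules in tumors typically contain
  both over- and under-expressed members; the exact fraction is
  inconsequential for every property tested). Cohort defaults are 34
  tumors and 6 normal controls, a small training-cohort scale.
* **Survival** — each tumor's composite planted activity z (standardized
  mean of up-minus-down module expression) sets an exponential event rate
  `baseline_hazard * exp(hazard_beta * z)` with `baseline_hazard = 0.01`
  events/month (median ~70 months at z = 0, a realistic breast-cancer
  scale), `hazard_beta = 1.5` per SD of activity, and independent
  Uniform(0, 120 months) censoring. ER status is an independent
  Bernoulli(0.75) label, so ER substratification has a well-defined null.

Every generator is a pure function of (config, seed); a single pipeline
seed fans out to per-stage seeds through a documented stage-name hash, so
stages are independently reproducible and two runs with the same seed are
byte-identical.

What the generator deliberately does **not** emulate: probe-level
microarray artifacts, batch effects, RNA-seq count distributions,
heteroscedastic or correlated background noise, overlapping modules, and
hazards beyond the proportional exponential model. Passing tests
demonstrate internal correctness and recoverability under this idealised
model, not performance on real cohorts.

# Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7) everywhere.
* Serialized floats carry 10 significant digits so byte-level determinism
  is testable; JSON key order is fixed.
* k-means: 1e-8 centroid tolerance, 300 iteration cap, assignment ties to
  the lower cluster index; all-identical samples short-circuit to a
  flagged degenerate single cluster.
* Zero-variance cases: genes with zero IQR in both classes are excluded
  from selection; zero-variance subnetworks are excluded from the
  composite with a warning; Welch tests on constant data return a flagged
  record with p = 1; log-rank with no events returns a flagged p = 1.
* Strict inequalities at thresholds: selection needs adjusted p < alpha;
  the high-risk group needs score > median.

# Problem sizes used by the test suite

The statistical acceptance checks simulate the training-cohort analog
(1000 genes, four 20-gene modules, 34/6 samples) over 20 seeds, a
460-tumor/62-normal transfer cohort per seed for the classifier, 50
survival cohorts of 500 tumors (plus 200 null cohorts), and 2000 null
Welch tests for calibration — sizes chosen to keep each property's
Monte-Carlo error a few percent while the whole suite stays comfortably
interactive.

# Known limitations

1. The training-set significance test is circular (see above); its
   family-wise null behaviour does not reach the nominal adjusted-p level.
2. Recursive bisection is divisive: once an early Fiedler cut splits a
   true module, recursion cannot reunite it, and in roughly half of the
   simulated studies one of four planted modules is fragmented enough to
   miss a clean top-4 ranking.
3. With very few normal controls the Welch test's Satterthwaite degrees
   of freedom are capped near the smaller group's size (df ≈ 7 at 6
   normals), which bounds attainable significance regardless of effect
   size.
4. Entropy ties are common (many candidates reach 0 or one-misassignment
   entropy); ranking then rests on the conductance tie-break.
5. The KNN vote fraction is a coarse ranking score for AUC.
6. Two classes only; multi-class selection is not supported.
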