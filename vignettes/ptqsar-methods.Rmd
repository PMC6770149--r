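---
title: "Methods: star-graph entropy descriptors and perturbation-theory features for epitope activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: star-graph entropy descriptors and perturbation-theory features for epitope activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptqsar)
```

## The modelling problem

Curated immune-epitope assay databases record, for each assay, a peptide
sequence, its measured activity class, and the conditions of the
experiment: the organism the epitope comes from, the host organism, the
in-vivo process, the experimental technique, and any adjuvant additive.
`ptqsar` models the activity class of a *query* epitope (ε_q ∈ {0, 1}:
positive-high vs positive-intermediate) given a *reference* epitope with
known activity ε_r, both considered under the same assay conditions. The
package implements the three stages of that model — sequence descriptors,
perturbation features, and a cross-validated classifier benchmark —
together with a synthetic assay-pair generator that makes every stage
testable end to end.

## Star-graph entropy descriptors

A peptide of length L becomes a graph with L + 1 nodes: one center node
and one node per sequence position. Positions sharing a residue letter
form a branch: they are chained in order of occurrence, and the first
occurrence is joined to the center. The result is a tree with one branch
per distinct residue, which encodes the *recurrence structure* of the
sequence — how often and how far apart each residue type reappears —
rather than its composition alone.

```{r star}
g <- build_star_graph("ACA")
g$edges        # rows: (from, to); node 1 is the center, node i+1 is position i
```

The descriptor family is the Shannon entropy of a random walk on this
graph. With Π the degree-normalized adjacency matrix (row-stochastic by
construction, positive exactly on the graph's edges) and p0 uniform over
all nodes, the node distribution after k steps is p(k) = p0 Π^k and

θ_k = −Σ_i p_i(k) ln p_i(k),  k = 0, …, 5,

in nats, with the convention 0 ln 0 = 0. Each θ_k lies in [0, ln(L + 1)];
θ_0 = ln(L + 1) exactly, so the k = 0 descriptor carries pure length
information while higher powers mix in branch topology.

```{r entropy}
round(peptide_entropy("AA"), 6)
```

Design choices a reader should know, all of them open points in the
descriptor lineage this package belongs to, fixed here as follows:

* **Logarithm base: natural.** Base choice only rescales the features and
  the benchmark standardizes per fold, so nothing downstream depends on it.
* **Initial distribution p0: uniform over all nodes, center included.**
  The simplest defensible choice; the center is an ordinary graph node and
  participates in Π and in the entropy sum. Excluding it would be an
  undocumented deviation from the graph actually built.
* **Graph variant: non-embedded by default.** An `embedded = TRUE` option
  adds consecutive-position backbone edges (duplicates with recurrence
  edges removed) for users who want sequence order retained on top of the
  recurrence branches; both variants are exposed rather than guessing a
  single truth.
* **Alphabet: any uppercase A–Z.** Nonstandard residue codes (B, J, O, U,
  X, Z) occur in curated databases and are accepted as their own branch
  types; rejecting them would silently shrink datasets.
* **k range 0…5.** The model consumes θ_0 and θ_5 only, but the full
  series costs nothing and aids diagnostics, so all six are emitted.

## Perturbation-theory features

Six condition factors are considered: the five categorical columns plus an
implicit `Seq` factor meaning "the whole collection of sequences". For a
factor c_j, the *perturbation* of a descriptor is its deviation from the
category mean (for `Seq`, the grand mean):

^qθ_k(c_j) = ^qθ_k − ⟨θ_k⟩_{c_j},

and the query–reference difference under identical conditions is
Δθ_k(c_j) = ^qθ_k(c_j) − ^rθ_k(c_j). The model's feature row is, in fixed
order: ε_r, ^qθ_5(Seq), ^qθ_0(Org), ^qθ_0(Tech), Δθ_5(Seq), Δθ_0(Host),
Δθ_0(Adju), Δθ_0(Proc), Δθ_0(Org), Δθ_0(Tech), with ε_q as the label.
ε_r enters as the raw observed class, not perturbed.

Three consequences of the exact construction deserve emphasis:

* **Means scope.** By default (`assemble_features()` with its default
  `means`), category means are computed on the full table — *reproduction
  mode*, matching how a precomputed feature table deposited alongside a
  study must have been built. A leakage-safe caller computes
  `compute_condition_means()` on training records only and passes them in;
  `unseen = "error"` (default) or `"grand_mean"` governs categories absent
  from the training split.
* **Shared means make the Δ columns degenerate.** Because query and
  reference perturbations subtract the *same* category mean, Δθ_k(c_j)
  collapses algebraically to ^qθ_k − ^rθ_k, identical across factors for a
  given k. The five Δθ_0 columns of one record are therefore equal. This
  follows directly from defining both perturbations against means built
  from query descriptors, the one consistent expectation per category; an
  alternative (reference-derived means for reference perturbations) would
  break the degeneracy but introduces a second, less interpretable
  expectation. The canonical 10-column layout is kept because the model
  contract fixes it, and tree ensembles are indifferent to duplicated
  columns (importance spreads across them, visible in the worked example).
* **Zero-sum and antisymmetry.** In reproduction mode the query
  perturbations of each category sum to zero (deviations from their own
  mean), and every Δ feature is exactly antisymmetric under query/reference
  swap. Both are enforced as tests.

**Deduplication.** Rows identical in all 10 features and the label are
collapsed to their first occurrence. Equality is string equality after
formatting features at 6 decimals — robust to float noise, reproducible
across platforms, and consistent with the 6-decimal CSV writers, so a
table round-tripped through disk deduplicates identically.

## The evaluation protocol

`run_benchmark()` applies, per stratified fold: standardization fitted on
the training split only (constant columns are centered, not scaled);
class-weighted training; AUROC on the held-out split. AUROC is computed by
midranks, algebraically the Mann–Whitney pair-counting probability with
half credit for ties, and is cross-checked in the tests against an
explicit all-pairs oracle.

* **Folds.** Within each class a seeded permutation is dealt round-robin,
  so per-fold class counts are within one of exact proportionality.
  Degenerate single-class folds abort with an error naming stratification.
* **Class weights.** Balanced weights w_c = N / (2 n_c), or the normalized
  variant rescaled so w_0 = 1. The two are proportional — at a 1.84:1
  imbalance they print as 0.77/1.42 and 1.00/1.84 — and train identically
  in learners that use only weight ratios; both are exposed because both
  parameterizations circulate.
* **Methods and defaults.** KNN (k = 5; votes are unweighted since nearest
  neighbors has no class-weight mechanism — flagged in the result, never
  silently ignored), linear and RBF SVM (`e1071`, class weights), logistic
  regression (`glm`, per-observation weights), decision tree (`rpart`,
  weights), random forest (`randomForest`, class priors; 10 trees for the
  seven-method comparison, 100 for a final model), and XGBoost (100
  rounds, the common toolkit default; imbalance via the positive-class
  weight ratio w_1/w_0). All other hyperparameters stay at their package
  defaults.
* **Seeding.** One top-level seed drives fold shuffling, and each
  (fold, method) fit gets a seed derived deterministically from it, so a
  run is exactly reproducible while methods remain decoupled. RNG state is
  saved and restored around every seeded section.
* **Tree scan and importance.** `rf_tree_scan()` reuses one fold
  assignment across all tree counts, so per-fold differences are paired
  and small AUROC gains are comparable. `rank_feature_importance()`
  normalizes impurity-decrease importances to sum to one within each fold
  before averaging, preventing folds with deeper forests from dominating.

## The synthetic generator

`synthetic_spec()` + `generate_dataset()` emulate the *shape* of curated
assay-pair data at desk scale: query and reference peptides of 5–30
residues over the 20-letter alphabet; five condition factors with
vocabulary sizes 50/20/15/28/30 (the 1448/323/15/28/505 factor structure
of the real database, scaled down); Zipf-skewed category frequencies
(exponent 1.1 — condition frequencies in curated databases are heavy
tailed, and uniform categories would make perturbations unrealistically
homogeneous); and a 1.84:1 class imbalance.

Labels are generated from features computed by the *real* descriptor and
feature path, so end-to-end tests exercise exactly the code users run. The
query class follows a logistic rule over the standardized features — by
default 2.0 on ε_r and 1.0 on Δθ_5(Seq), plus an interaction term
2.5·z(Δθ_5(Seq))·z(Δθ_0(Org)) that plants non-linear structure no linear
model can represent — then labels flip at a 5% noise rate (ordinary assay
label noise). The intercept is calibrated by root finding so the
*post-noise* expected class ratio hits the imbalance target; flipping at
rate ρ maps a mean p to p(1 − 2ρ) + ρ, so targets outside the reachable
band are rejected as infeasible rather than silently missed.

What the generator does **not** emulate: biologically realistic sequence
motifs, the true joint distribution of organisms and hosts, and any real
dependence of activity on physicochemistry. Passing tests therefore
demonstrate that the pipeline's algebra and protocol behave as specified
on data of the right shape — not that the model predicts real epitope
activity at any particular level.

## Problem sizes and numerical choices

The validation suite works at sizes chosen to make every property
measurable with comfortable margins on a single CPU: 10,000 records for
the perturbation-algebra checks, 20,000 for the linear-vs-nonlinear
ordering and the tree scan, 2,000 per seed (five seeds) for
planted-importance recovery, and 100 random peptides for the descriptor
oracle. Tolerances: 1e-9 against the entropy oracle and for per-category
zero sums, exact equality for Δ antisymmetry and the AUROC pair-counting
oracle, 1e-10 for row-stochasticity of matrix powers.

## Limitations

* The headline cross-validated AUROCs reported for the full deposited
  feature table of roughly 709,100 assay pairs require that external
  table; this package ships reproduction-mode ingestion for users who hold
  it but does not download or bundle it, and synthetic desk-scale numbers
  are not comparable to full-scale ones.
* Reproduction-mode means are computed on the full table and thus leak
  test-fold information into the features (not into the scaling, which is
  always per fold). That is faithful to how precomputed feature tables are
  built; the leakage-safe mode exists for sound de novo evaluation.
* Pair assignment (which reference is matched to which query) is taken as
  given in the input table; rebuilding it from raw database exports is out
  of scope.
* Only Shannon-entropy descriptors are implemented; other graph indices
  (Wiener, connectivity, spectral moments) and physicochemical node
  weights are not.
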