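# ptqsar

Perturbation-theory QSAR modelling of linear B-cell epitope activity from
star-graph Shannon-entropy descriptors of peptide sequences.

## The problem

Peptide vaccine design needs to know, before synthesis, whether a candidate
epitope will raise a strong immune response. Curated assay databases record
the activity of known epitopes together with the conditions of each assay —
epitope organism, host organism, in-vivo process, experimental technique,
adjuvant additive. This package predicts the activity class of a **query**
peptide (positive-high, ε = 1, vs positive-intermediate, ε = 0) from a
**reference** peptide whose activity is already known, with both sequences
observed under the same experimental conditions.

It is aimed at cheminformatics and immunoinformatics practitioners who want
a self-contained, reproducible implementation of the descriptor algebra and
the evaluation protocol, with a synthetic assay-pair generator so that every
stage can be validated without any external download.

## The model

**Descriptors.** A peptide of length L is embedded as a *star graph*
(sequence recurrence network) with L + 1 nodes: a center plus one branch per
residue type, occurrences of the same residue chained in sequence order and
the first occurrence joined to the center. The transition matrix Π is the
degree-normalized adjacency, and with a uniform initial distribution p0 the
descriptors are the Shannon entropies of the propagated node distribution:

θ_k = −Σ_i p_i(k) · ln p_i(k),  p(k) = p0 · Π^k,  k = 0 … 5.

**Perturbation features.** For a condition factor c_j (Seq, Org, Host, Proc,
Tech, Adju), the perturbation of a descriptor is its deviation from the
category mean of that factor, ^qθ_k(c_j) = ^qθ_k − ⟨θ_k⟩_{c_j}, and
Δθ_k(c_j) = ^qθ_k(c_j) − ^rθ_k(c_j) contrasts query and reference under the
identical conditions. The model's 10 inputs are, in order:

ε_r, ^qθ_5(Seq), ^qθ_0(Org), ^qθ_0(Tech), Δθ_5(Seq), Δθ_0(Host),
Δθ_0(Adju), Δθ_0(Proc), Δθ_0(Org), Δθ_0(Tech)

with ε_q as the binary label.

**Evaluation.** Stratified five-fold cross-validation with per-fold
standardization (fitted on the training split only), class-weighted training
of seven classifiers (KNN, linear SVM, RBF SVM, logistic regression,
decision tree, random forest, XGBoost), and AUROC — the Mann–Whitney
concordance probability with half credit for ties — on each held-out fold.
A random-forest tree-count scan over paired folds and fold-averaged
impurity importances complete the protocol.

## Worked example

```r
library(ptqsar)

## entropy descriptors of the dipeptide "AA" (3-node path graph)
round(peptide_entropy("AA"), 6)
#>   theta0   theta1   theta2   theta3   theta4   theta5
#> 1.098612 0.867563 1.098612 0.867563 1.098612 0.867563
```

θ_0 = ln 3 is the uniform-start entropy over the three nodes; the chain is
bipartite, so the distribution (and the entropy) oscillates with k.

```r
## synthetic assay pairs with planted non-linear signal, end to end
d <- generate_dataset(synthetic_spec(n_records = 2000, seed = 11))
table(d$features$label)
#>    0    1
#> 1308  692

bench <- run_benchmark(d$features,
                       benchmark_config(methods = c("lr", "dt", "rf"), seed = 3))
bench
#> Stratified 5-fold AUROC benchmark (seed 3, balanced class weights)
#> class weights: 0: 0.76, 1: 1.45
#>  method  fold1  fold2  fold3  fold4  fold5   mean       sd
#>      lr 0.6545 0.6349 0.7002 0.7387 0.6789 0.6814 0.040369
#>      dt 0.8284 0.8301 0.8242 0.8064 0.8244 0.8227 0.009445
#>      rf 0.8345 0.8283 0.8157 0.8377 0.8468 0.8326 0.011569
```

The class ratio tracks the 1.84:1 imbalance typical of curated epitope assay
data, and the tree-based learners clearly beat the linear baseline because
the generator plants an interaction between two perturbation features that
logistic regression cannot represent.

```r
imp <- rank_feature_importance(d$features, benchmark_config(rf_trees = 100, seed = 3))
head(as.data.frame(imp)[, 1:2], 3)
#>         feature importance
#> 1  d_theta5_seq  0.1887989
#> 2 d_theta0_tech  0.1052675
#> 3 d_theta0_host  0.1007806
```

A command-line front end covering descriptor calculation, feature assembly,
benchmarking, the tree scan, importance ranking, and synthetic-data
generation is installed at
`system.file("cli/epitope-ptqsar.R", package = "ptqsar")`.

Users holding a full deposited feature table (10 features + label) can run
the same protocol on it in reproduction mode: `read_feature_table()` maps
external column names through a case-insensitive alias table, and
`deduplicate()`, `run_benchmark()`, `rf_tree_scan()` and
`rank_feature_importance()` operate on the result unchanged.

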