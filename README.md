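# iefs — iterative ensemble feature selection for imbalanced multiclass expression data

`iefs` selects per-class gene signatures and classifies samples in
multiclass gene-expression studies where the classes are strongly
imbalanced — the usual situation in tumour-type panels, where one common
type contributes tens of samples and rare types a handful. It is aimed at
computational biologists who want a small, interpretable gene list per
class together with an honest estimate of minority-class sensitivity.

## The method

The K-class problem is decomposed One-Versus-All (OVA): one binary task per
class, class *k* against the rest. OVA makes imbalance worse (the "rest"
side always outnumbers the target class), so within each binary task
balanced sampling and filter feature selection *alternate* over `T` steps.
With majority/minority sizes `S_M`, `S_m`, full feature count `N_M` and
target signature size `N_n`, each step moves

```
M_i = (S_M − S_m) / T   samples toward balance
N_i = (N_M − N_n) / T   features out of the task
```

(floored, last step absorbing the remainder). Sampling is random
undersampling of the majority or SMOTE oversampling of the minority
(synthetic points `x + u·(x_nn − x)`, `u ~ U[0,1)`, `x_nn` among the 5
nearest minority neighbours); selection is one of three filters on
discretized expression:

* **ranking** — mutual information `I(f; c)`, top `n`;
* **FCBF** — symmetric uncertainty `SU = 2I/(H+H)` ranking with threshold
  `δ` and pairwise redundancy removal (`SU(c;f_j) ≥ SU(c;f_i)` and
  `SU(f_i;f_j) ≥ SU(f_i;c)` ⇒ drop `f_i`);
* **mRMR** — greedy `max_j [ I(f_j;c) − (1/(m−1)) Σ_{f_i∈S} I(f_i;f_j) ]`
  over a top-50 relevance pool.

Each task ends balanced with an `N_n`-gene signature and a binary
classifier (KNN, K = 3, or linear SVM); prediction is by majority vote of
the K members with a documented confidence → class-size → class-order tie
rule. Evaluation is stratified 3- or 10-fold cross-validation (3 when the
smallest class has under 10 samples) reporting accuracy and macro
one-vs-rest AUC, both in percent.

## Worked example

```r
library(iefs)

# 5 classes, sizes 100/20/20/20/20, 1000 genes, 15 informative per class
sim <- simulate_expression(class_sizes = c(100, 20, 20, 20, 20),
                           n_features = 1000, n_informative = 15,
                           effect_size = 1.5, seed = 1)

cfg <- run_config(selector = "ranking", sampler = "oversample",
                  T_steps = 4, n_features = 30, seed = 1)
fit <- iefs_fit(sim$data, cfg)
fit
#> <iefs_ensemble> 5 one-vs-all members | ranking + oversample | T = 4, N_n = 30, knn
#>   C1            30 features
#>   C2            30 features
#>   C3            30 features
#>   C4            30 features
#>   C5            30 features

head(tidy(fit))           # one row per (class, signature gene)
#> # A tibble: 6 × 4
#>   class feature  rank short
#>   <chr> <chr>   <int> <lgl>
#> 1 C1    g0001       1 FALSE
#> 2 C1    g0014       2 FALSE
#> 3 C1    g0011       3 FALSE
#> 4 C1    g0009       4 FALSE
#> 5 C1    g0013       5 FALSE
#> 6 C1    g0004       6 FALSE

cv <- iefs_cv(sim$data, cfg)
cv[, c("accuracy", "auc")]
#> # A tibble: 1 × 2
#>   accuracy   auc
#>      <dbl> <dbl>
#> 1      100  99.8

round(cv$per_class_recall[[1]], 1)
#>  C1  C2  C3  C4  C5
#> 100 100 100 100 100
```

The signature for class C1 leads with genes `g0001`, `g0014`, `g0011`, … —
members of C1's planted informative block (`g0001`–`g0015`), recovered from
1000 candidates. Ten-fold stratified cross-validation (chosen automatically:
the smallest class has 20 samples) gives 100% accuracy and 99.8% macro AUC
on this synthetic scenario, with every minority class at 100% recall —
the quantity OVA classification typically sacrifices without balancing.

`iefs_benchmark()` sweeps signature sizes 5–100 against selectors,
samplers and `T`, and `autoplot()` draws the accuracy/AUC-versus-size
curves. A command-line front end (`inst/cli/iefs.R`) exposes `select`,
`fit`, `predict`, `benchmark` and `simulate` for shell pipelines; datasets
are plain sample-major TSV/CSV or GCT 1.2 with a label sidecar.

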