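# wkpca — weighted kernel PCA for gene-expression data

Gene-expression matrices are wide and short: thousands of genes, a few
dozen to a few hundred samples, and most genes carry no information about
the phenotype. Feeding such matrices to a classifier directly is slow and
often counterproductive. `wkpca` implements a nonlinear dimension-reduction
method for this regime: **weighted kernel principal component analysis**,
in which several kernels — including a family of t-distribution-derived
kernels — are combined with data-driven weights, and samples are projected
onto the leading eigenvectors of the combined Gram matrix.

The package is aimed at analysts benchmarking classifiers on
high-dimensional omics data, and at anyone needing a self-contained kernel
PCA with multiple-kernel weighting in base R.

## The method

Given samples $x_1, \dots, x_m \in \mathbb{R}^p$ and kernels
$\kappa_1, \dots, \kappa_q$ with Gram matrices $K_s$:

1. each kernel's spectrum $\lambda^s_1 \ge \lambda^s_2 \ge \dots$ sets its
   weight from the leading partial sums,
   $\omega_s = \sum_{j \le d} \lambda^s_j \big/ \sum_{s'} \sum_{j \le d} \lambda^{s'}_j$;
2. the weighted Gram matrix $K = \sum_s \omega_s K_s$ (a valid kernel
   matrix, since a convex combination of PSD matrices is PSD) is
   eigendecomposed, $K\alpha^j = \lambda_j \alpha^j$;
3. the retained dimension $d$ is the smallest with cumulative efficiency
   $R_d = \sum_{j \le d}\lambda_j / \sum_j \lambda_j \ge 0.8$ (weights and
   spectrum recomputed per candidate $d$, since the weights depend on it);
4. any sample $x$ is embedded by
   $z_j(x) = \sum_i \alpha_{ij}\, \kappa_w(x_i, x)$, evaluated as one
   vectorized cross-kernel block.

The t-class kernels are functions of the Euclidean distance $r$: the
t-density kernel, its Cauchy special case $1/(\pi(1+r^2))$, the pseudo-t
kernel $1/(\pi(1+r))$ and the multi-scale t kernel $1/(c(1+r))$. Preset
combinations `eq33`, `eq34`, `eq35` pair them (optionally with a Gaussian
or Laplace kernel) at the published scales $c_1 = 0.1$, $c_2 = 0.2$,
$\gamma = 0.1$.

For evaluation the package provides macro-averaged precision/recall/F1,
the Hand–Till multiclass AUC, a seeded nested cross-validation harness
around standard classifiers (naive Bayes, RBF-SVM, k-NN, random forest,
iterative random forest), and the **optimal performance rate** statistics:
OPR is the fraction of (classifier × dataset × metric) cells of a
benchmark grid in which the weighted-kernel strategy attains the maximum
(ties count); COPR accumulates runner-up ranks.

## Worked example

```r
library(wkpca)

# a synthetic cohort in the target regime: 150 samples, 500 genes,
# 3 classes, nonlinear class structure, 90% pure-noise genes
d <- simulate_expression(synth_spec(n = 150, p = 500, k = 3, seed = 1))
train <- seq_len(100); test <- 101:150

fit <- wkpca(d$x[train, ], kernels = "eq34", threshold = 0.8)
fit
#> Weighted kernel PCA: 100 samples x 500 features -> 10 components
#> kernels and weights:
#>   gaussian       w = 0.0771
#>   multiscale_t   w = 0.6477
#>   multiscale_t   w = 0.2751
#> cumulative efficiency R_d = 0.8029 (threshold 0.80)
```

The fit kept 10 of 500 dimensions (the smallest $d$ whose weighted
spectrum passes 80% cumulative efficiency) and gave most weight to the two
multi-scale t kernels. Held-out samples are embedded with `predict()` and
classified in the reduced space:

```r
knn  <- caret::knn3(fit$scores, d$labels[train], k = 5)
pred <- predict(knn, predict(fit, d$x[test, ]), type = "class")
prob <- predict(knn, predict(fit, d$x[test, ]), type = "prob")
macro_metrics(d$labels[test], pred, scores = prob)
#> accuracy 0.9800 | macroP 0.9815 | macroR 0.9792 | macroF1 0.9797 | AUC 0.9979
```

Ten embedding coordinates support 98% held-out accuracy on data where 450
of 500 genes are pure noise. The OPR summary of the packaged benchmark
grid (five classifiers × four reduction strategies × six public expression
cohorts × four metrics):

```r
rate <- opr(load_results_table())
sprintf("OPR = %d/%d = %.4f", attr(rate, "attained"), attr(rate, "cells"), rate)
#> "OPR = 71/120 = 0.5917"
```

The weighted-kernel strategy is the best performer in 71 of the 120
benchmark cells.

A thin command-line wrapper ships in `inst/cli/wkpca.R`
(`simulate`, `reduce`, `opr`, `copr` subcommands; every output gets a JSON
sidecar with the resolved parameters and seed).

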