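# independent brute-force oracles used across the suite: every one of these
# walks pairs or classes in explicit scalar loops, the opposite of the
# vectorized implementation paths they check

loop_distance_matrix <- function(X) {
  m <- nrow(X)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  D
}

loop_inner_product_matrix <- function(X) {
  m <- nrow(X)
  G <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    G[i, j] <- sum(X[i, ] * X[j, ])
  G
}

loop_kernel_matrix <- function(spec, X) {
  m <- nrow(X)
  K <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    arg <- if (spec$arg_kind == "distance")
      sqrt(sum((X[i, ] - X[j, ])^2)) else sum(X[i, ] * X[j, ])
    K[i, j] <- kernel_value(spec, arg)
  }
  K
}

# projection of new samples by the explicit double summation
# z_j(x) = sum_i alpha_ij kappa_w(x_i, x)
loop_transform <- function(model, Xnew) {
  m <- nrow(model$x)
  Z <- matrix(0, nrow(Xnew), model$d)
  for (r in seq_len(nrow(Xnew))) for (j in seq_len(model$d)) {
    acc <- 0
    for (i in seq_len(m)) {
      kv <- 0
      for (s in seq_along(model$kernels)) {
        sp <- model$kernels[[s]]
        arg <- if (sp$arg_kind == "distance")
          sqrt(sum((model$x[i, ] - Xnew[r, ])^2)) else
          sum(model$x[i, ] * Xnew[r, ])
        kv <- kv + model$weights[s] * kernel_value(sp, arg)
      }
      acc <- acc + model$alpha[i, j] * kv
    }
    Z[r, j] <- acc
  }
  Z
}

# one-vs-rest confusion counting, class by class
loop_macro_metrics <- function(y_true, y_pred) {
  classes <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  yt <- as.character(y_true); yp <- as.character(y_pred)
  P <- R <- F1 <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- sum(yt == cl & yp == cl)
    fp <- sum(yt != cl & yp == cl)
    fn <- sum(yt == cl & yp != cl)
    P[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
    R[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
    F1[ci] <- if (P[ci] + R[ci] > 0)
      2 * P[ci] * R[ci] / (P[ci] + R[ci]) else 0
  }
  list(accuracy = mean(yt == yp), macro_precision = mean(P),
       macro_recall = mean(R), macro_f1 = mean(F1))
}

# exhaustive cross-class pair counting for the multiclass AUC
loop_hand_till_auc <- function(y_true, scores) {
  yt <- as.character(y_true)
  classes <- sort(unique(yt))
  pair_vals <- c()
  for (a in seq_along(classes)) for (b in seq_along(classes)) {
    if (a >= b) next
    i <- classes[a]; j <- classes[b]
    ii <- which(yt == i); jj <- which(yt == j)
    cnt_ij <- 0
    for (u in ii) for (v in jj)
      cnt_ij <- cnt_ij + (scores[u, i] > scores[v, i]) +
        0.5 * (scores[u, i] == scores[v, i])
    cnt_ji <- 0
    for (u in jj) for (v in ii)
      cnt_ji <- cnt_ji + (scores[u, j] > scores[v, j]) +
        0.5 * (scores[u, j] == scores[v, j])
    a_ij <- cnt_ij / (length(ii) * length(jj))
    a_ji <- cnt_ji / (length(ii) * length(jj))
    pair_vals <- c(pair_vals, (a_ij + a_ji) / 2)
  }
  mean(pair_vals)
}

# every kernel family at the parameter settings exercised in the PSD suite
all_test_specs <- function() {
  c(list(kernel_spec("gaussian", gamma = 0.1),
         kernel_spec("laplace", gamma = 0.1),
         kernel_spec("cauchy"),
         kernel_spec("pseudo_t")),
    lapply(c(1, 5, 30, 100), function(n) kernel_spec("t_density", df = n)),
    lapply(c(0.1, 0.2, 1, 5), function(cc) kernel_spec("multiscale_t",
                                                       c = cc)),
    list(kernel_spec("multiscale_t", c = 0.1, on_squared_distance = TRUE),
         kernel_spec("linear"),
         kernel_spec("polynomial", degree = 2, offset = 1),
         kernel_spec("tanh", slope = 0.1, offset = 0)))
}

# the families with a positive semi-definiteness guarantee: all distance
# families plus the PSD inner-product ones; the sigmoid (tanh) kernel is
# indefinite by construction and carries no such guarantee
psd_test_specs <- function() {
  specs <- all_test_specs()
  specs[vapply(specs, function(s) s$family != "tanh", TRUE)]
}

# drop the bookkeeping attributes a kernel matrix carries before comparing
unclass_attr <- function(K) {
  attributes(K) <- list(dim = dim(K))
  K
}

random_dataset <- function(m, p, scale = 5) {
  matrix(stats::runif(m * p, -scale, scale), m, p)
}

# a small complete results grid for opr/copr unit tests
toy_results <- function(wk_value, other_values = c(0.5, 0.6, 0.7),
                        strategies = c("AV", "PCA", "SKPCA", "WKPCA")) {
  rows <- expand.grid(dataset = c("D1", "D2"), classifier = c("c1", "c2"),
                      metric = c("m1", "m2"), strategy = strategies,
                      stringsAsFactors = FALSE)
  rows$value <- ifelse(rows$strategy == "WKPCA", wk_value,
                       other_values[match(rows$strategy,
                                          setdiff(strategies, "WKPCA"))])
  as_results_table(rows)
}
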