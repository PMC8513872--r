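test_that("kernel eigendecomposition is sorted, orthonormal and exact", {
  e <- eigendecompose_kernel(diag(4))
  expect_equal(e$values, rep(1, 4))
  e <- eigendecompose_kernel(diag(c(2, 1)))
  expect_equal(e$values, c(2, 1))
  expect_equal(abs(e$vectors), diag(2))
  set.seed(9)
  A <- matrix(rnorm(144), 12)
  K <- crossprod(A)
  e <- eigendecompose_kernel(K)
  expect_true(all(diff(e$values) <= 1e-12))
  expect_equal(crossprod(e$vectors), diag(12), tolerance = 1e-8)
  recon <- e$vectors %*% diag(e$values) %*% t(e$vectors)
  expect_equal(recon, K, tolerance = 1e-8)
})

test_that("eigenvalue-ratio weights are correct and on the simplex", {
  expect_equal(compute_kernel_weights(list(c(3, 1)), d = 1), 1)
  expect_equal(compute_kernel_weights(list(c(4, 2, 1), c(2, 1, 1)), d = 2),
               c(2 / 3, 1 / 3))
  set.seed(13)
  for (rep in 1:100) {
    spectra <- lapply(1:3, function(i)
      sort(c(runif(8, 0, 10), -runif(2, 0, 1e-6)), decreasing = TRUE))
    d <- sample(1:8, 1)
    w <- compute_kernel_weights(spectra, d)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  expect_error(compute_kernel_weights(list(c(0, 0), c(0, 0)), 1),
               "degenerate")
})

test_that("cumulative efficiency is the partial-sum ratio", {
  expect_equal(cumulative_efficiency(c(4, 3, 2, 1), 2), 0.7)
  expect_equal(cumulative_efficiency(c(4, 3, 2, 1), 4), 1)
  set.seed(17)
  lam <- sort(runif(12, 0, 5), decreasing = TRUE)
  for (d in 1:12)
    expect_equal(cumulative_efficiency(lam, d),
                 sum(lam[1:d]) / sum(lam), tolerance = 1e-12)
  effs <- vapply(1:12, cumulative_efficiency, numeric(1), lambda = lam)
  expect_true(all(diff(effs) >= 0))
  expect_error(cumulative_efficiency(c(0, 0), 1), "degenerate")
})

test_that("dimension selection brackets the threshold", {
  expect_equal(select_dimension(c(5, 3, 1, 1), 0.8), 2)
  expect_equal(select_dimension(c(1, 0, 0), 0.5), 1)
  set.seed(19)
  for (rep in 1:50) {
    lam <- sort(runif(sample(3:15, 1), 0, 5), decreasing = TRUE)
    th <- runif(1, 0.05, 1)
    d <- select_dimension(lam, th)
    expect_gte(cumulative_efficiency(lam, d), th - 1e-12)
    if (d > 1) expect_lt(cumulative_efficiency(lam, d - 1), th)
  }
})

test_that("a centered linear kernel reproduces classical PCA scores", {
  set.seed(31)
  x <- matrix(rnorm(20 * 6), 20)
  fit <- wkpca(x, kernel_spec("linear"), d = 5, centered = TRUE,
               alpha_scaling = "feature_space")
  pc <- prcomp(x, center = TRUE)
  for (j in 1:5) {
    err <- min(max(abs(fit$scores[, j] - pc$x[, j])),
               max(abs(fit$scores[, j] + pc$x[, j])))
    expect_lt(err, 1e-8)
  }
})

test_that("a single kernel gets weight one and matches plain KPCA", {
  set.seed(37)
  x <- matrix(rnorm(15 * 5), 15)
  fit <- wkpca(x, kernel_spec("gaussian", gamma = 0.1), d = 4)
  expect_equal(fit$weights, 1)
  K <- kernel_matrix(kernel_spec("gaussian", gamma = 0.1), x)
  e <- eigendecompose_kernel(K)
  expect_equal(fit$lambda, e$values, tolerance = 1e-10)
  expect_equal(abs(fit$scores),
               abs(K %*% e$vectors[, 1:4]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the fitted weighted spectrum matches independent recomposition", {
  set.seed(41)
  x <- matrix(rnorm(30 * 50), 30)
  fit <- wkpca(x, "eq34", d = 6)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  K <- weighted_kernel_matrix(fit$kernels, fit$weights, x)
  expect_equal(fit$lambda, eigendecompose_kernel(K)$values,
               tolerance = 1e-10)
})

test_that("automatic dimension selection follows the per-candidate loop", {
  set.seed(43)
  x <- matrix(rnorm(25 * 8), 25) * 0.3
  fit <- wkpca(x, "eq33", threshold = 0.8)
  # the stored weights are the ones recomputed at the retained d
  expect_equal(fit$weights,
               compute_kernel_weights(fit$lambda_by_kernel, fit$d))
  expect_gte(cumulative_efficiency(fit$lambda, fit$d), 0.8 - 1e-12)
  if (fit$d > 1) {
    w_prev <- compute_kernel_weights(fit$lambda_by_kernel, fit$d - 1L)
    K_prev <- weighted_kernel_matrix(fit$kernels, w_prev, x)
    lam_prev <- eigendecompose_kernel(K_prev)$values
    expect_lt(cumulative_efficiency(lam_prev, fit$d - 1L), 0.8)
  }
  expect_error(wkpca(x, "eq33", d = 26), "1 <= d <= m")
})

test_that("projection matches the explicit double-summation", {
  set.seed(47)
  x <- matrix(rnorm(18 * 6), 18)
  fit <- wkpca(x, "eq34", d = 5)
  # training data: column j of the embedding is lambda_j * alpha_j
  expect_equal(unname(fit$scores),
               fit$alpha[, 1:5] %*% diag(fit$lambda[1:5]),
               tolerance = 1e-8)
  self <- predict(fit, x)
  expect_equal(unname(self), unname(fit$scores), tolerance = 1e-8)
  # a new sample duplicating training sample 3 lands on its embedding
  dup <- predict(fit, x[3, , drop = FALSE])
  expect_equal(unname(dup), unname(fit$scores[3, , drop = FALSE]),
               tolerance = 1e-8)
  xnew <- matrix(rnorm(4 * 6), 4)
  expect_equal(unname(predict(fit, xnew)), loop_transform(fit, xnew),
               tolerance = 1e-10)
  expect_error(predict(fit, matrix(0, 2, 5)), "features")
})

test_that("reordering training samples permutes the embedding rows", {
  set.seed(53)
  x <- matrix(rnorm(16 * 4), 16)
  perm <- sample(16)
  f1 <- wkpca(x, "eq33", d = 3)
  f2 <- wkpca(x[perm, ], "eq33", d = 3)
  for (j in 1:3) {
    a <- f1$scores[perm, j]; b <- f2$scores[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("fit surface validates input and prints cleanly", {
  expect_error(wkpca(matrix(1, 1, 3)), "two samples")
  expect_error(wkpca(matrix(1, 4, 3), kernels = list()), "kernel_spec")
  set.seed(59)
  fit <- wkpca(matrix(rnorm(12 * 3), 12), "gaussian", d = 2)
  expect_output(print(fit), "kernels and weights")
  expect_output(print(summary(fit)), "cumulative efficiency")
  expect_equal(weights(fit), fit$weights)
})
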