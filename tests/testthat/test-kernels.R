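test_that("pairwise Euclidean distances match direct computation", {
  expect_equal(pairwise_distance_matrix(matrix(3, 1, 1)),
               matrix(0, 1, 1))
  expect_equal(pairwise_distance_matrix(rbind(c(0, 0), c(3, 4))),
               matrix(c(0, 5, 5, 0), 2))
  set.seed(42)
  X <- random_dataset(6, 4)
  D <- pairwise_distance_matrix(X)
  expect_equal(D, loop_distance_matrix(X), tolerance = 1e-12)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), rep(0, 6))
})

test_that("inner-product matrices match direct computation", {
  expect_equal(inner_product_matrix(diag(2)), diag(2))
  expect_equal(inner_product_matrix(matrix(2, 1, 1)), matrix(4, 1, 1))
  set.seed(7)
  X <- random_dataset(5, 3)
  expect_equal(inner_product_matrix(X), loop_inner_product_matrix(X),
               tolerance = 1e-12)
})

test_that("non-finite input is rejected with the offending row named", {
  X <- matrix(1, 3, 2); X[2, 1] <- NA
  expect_error(pairwise_distance_matrix(X), "row: 2")
  expect_error(inner_product_matrix(X), "row: 2")
  expect_error(min_eigenvalue(matrix(c(1, NA, NA, 1), 2)), "non-finite")
})

test_that("kernel values follow their closed forms", {
  expect_equal(kernel_value(kernel_spec("gaussian", gamma = 2.7), 0), 1)
  expect_equal(kernel_value(kernel_spec("multiscale_t", c = 0.2), 0), 5)
  expect_equal(kernel_value(kernel_spec("cauchy"), 1), 1 / (2 * pi))
  expect_equal(kernel_value(kernel_spec("pseudo_t"), 0), 1 / pi)
  # the t-density kernel IS the Student-t density: dt() is the independent
  # gamma-function oracle, and at df = 30 it is near the standard normal
  for (r in c(0, 0.5, 1, 2.5)) {
    expect_equal(kernel_value(kernel_spec("t_density", df = 30), r),
                 dt(r, df = 30), tolerance = 1e-6)
  }
  expect_lt(abs(kernel_value(kernel_spec("t_density", df = 30), 0) -
                  dnorm(0)), 0.01)
  # Cauchy kernel is the df = 1 special case
  expect_equal(kernel_value(kernel_spec("cauchy"), 1.3),
               kernel_value(kernel_spec("t_density", df = 1), 1.3),
               tolerance = 1e-12)
})

test_that("parameter and domain constraints are enforced", {
  expect_error(kernel_spec("gaussian", gamma = 0), "positive")
  expect_error(kernel_spec("gaussian", gamma = -1), "positive")
  expect_error(kernel_spec("multiscale_t", c = 0), "positive")
  expect_error(kernel_spec("t_density", df = 0), ">= 1")
  expect_error(kernel_spec("t_density", df = 2.5), ">= 1")
  expect_error(kernel_spec("polynomial", degree = 0), ">= 1")
  expect_error(kernel_value(kernel_spec("gaussian"), -0.1), "negative")
  # inner-product kernels accept negative arguments
  expect_equal(kernel_value(kernel_spec("linear"), -2), -2)
})

test_that("Gram construction applies the kernel to the whole matrix", {
  expect_equal(unclass_attr(kernel_matrix(kernel_spec("pseudo_t"),
                                          matrix(1.5, 1, 2))),
               matrix(1 / pi, 1, 1))
  K <- kernel_matrix(kernel_spec("gaussian", gamma = 0.1),
                     rbind(c(0, 0), c(3, 4)))
  expect_equal(unclass_attr(K),
               matrix(c(1, exp(-2.5), exp(-2.5), 1), 2))
  set.seed(11)
  X <- random_dataset(8, 5)
  for (spec in all_test_specs()) {
    K <- kernel_matrix(spec, X)
    expect_equal(unclass_attr(K), loop_kernel_matrix(spec, X),
                 tolerance = 1e-12,
                 label = paste("family", spec$family))
  }
})

test_that("precomputed argument matrices are validated", {
  X <- random_dataset(4, 3)
  D <- pairwise_distance_matrix(X)
  expect_equal(kernel_matrix(kernel_spec("cauchy"), X),
               kernel_matrix(kernel_spec("cauchy"), precomputed = D))
  expect_error(kernel_matrix(kernel_spec("cauchy"), X,
                             precomputed = D[1:3, ]), "square")
  expect_error(kernel_matrix(kernel_spec("cauchy"), X[1:3, ],
                             precomputed = D), "shape")
})

test_that("weighted combinations are convex and validated", {
  set.seed(3)
  X <- random_dataset(6, 4)
  g <- kernel_spec("gaussian", gamma = 0.1)
  expect_equal(unclass_attr(weighted_kernel_matrix(list(g), 1, X)),
               unclass_attr(kernel_matrix(g, X)))
  expect_equal(unclass_attr(weighted_kernel_matrix(list(g, g),
                                                   c(0.5, 0.5), X)),
               unclass_attr(kernel_matrix(g, X)))
  expect_error(weighted_kernel_matrix(list(g, g), c(0.7, 0.4), X),
               "sum to 1")
  expect_error(weighted_kernel_matrix(list(g, g), c(1.2, -0.2), X),
               "nonnegative")
  expect_error(weighted_kernel_matrix(list(g, g), 1, X), "length")
  # linear in the weights: the convex path hits both endpoint matrices
  h <- kernel_spec("cauchy")
  K0 <- unclass_attr(kernel_matrix(g, X))
  K1 <- unclass_attr(kernel_matrix(h, X))
  for (w in c(0, 0.3, 1)) {
    Kw <- unclass_attr(weighted_kernel_matrix(list(g, h), c(w, 1 - w), X))
    expect_equal(Kw, w * K0 + (1 - w) * K1, tolerance = 1e-12)
  }
})

test_that("min_eigenvalue matches known spectra", {
  expect_equal(min_eigenvalue(diag(3)), 1)
  expect_equal(min_eigenvalue(matrix(1, 2, 2)), 0)
  set.seed(5)
  K <- kernel_matrix(kernel_spec("gaussian", gamma = 0.1),
                     random_dataset(20, 5))
  expect_gte(min_eigenvalue(K), -1e-8 * sum(diag(K)))
})

test_that("every kernel family yields numerically PSD Gram matrices", {
  # small-scale version of the full positive semi-definiteness sweep
  set.seed(101)
  specs <- psd_test_specs()
  for (rep in 1:25) {
    X <- random_dataset(sample(2:20, 1), sample(1:8, 1))
    for (spec in specs) {
      K <- kernel_matrix(spec, X)
      expect_gte(min_eigenvalue(K), -1e-8 * abs(sum(diag(K))))
    }
  }
})

test_that("distance-family Grams are translation invariant", {
  set.seed(23)
  X <- random_dataset(10, 4)
  shift <- matrix(rnorm(4), 10, 4, byrow = TRUE)
  for (spec in all_test_specs()) {
    if (spec$arg_kind != "distance") next
    expect_equal(unclass_attr(kernel_matrix(spec, X)),
                 unclass_attr(kernel_matrix(spec, X + shift)),
                 tolerance = 1e-9)
  }
})
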