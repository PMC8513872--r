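#' Kernel specifications
#'
#' A kernel specification names a kernel family and its scalar parameters.
#' Distance-based families (\code{gaussian}, \code{laplace}, \code{t_density},
#' \code{cauchy}, \code{pseudo_t}, \code{multiscale_t}) are evaluated on the
#' Euclidean distance between two samples; inner-product families
#' (\code{linear}, \code{polynomial}, \code{tanh}) are evaluated on their
#' inner product.
#'
#' The t-class kernels are derived from the Student-t density:
#' \code{t_density} is the t density itself with \code{df} degrees of freedom,
#' \code{cauchy} is its \code{df = 1} special case \eqn{1/(\pi(1+r^2))},
#' \code{pseudo_t} replaces the squared argument by the plain distance,
#' \eqn{1/(\pi(1+r))}, and \code{multiscale_t} generalizes the latter to
#' \eqn{1/(c(1+r))} with a free scale \eqn{c > 0} (small scales adapt to
#' sharply varying data, large scales to smooth data). With
#' \code{on_squared_distance = TRUE} the multi-scale form is applied to the
#' squared distance, \eqn{1/(c(1+r^2))}.
#'
#' @param family Kernel family name (see Details).
#' @param gamma Positive rate for \code{gaussian} (\eqn{e^{-\gamma r^2}}) and
#'   \code{laplace} (\eqn{e^{-\gamma r}}).
#' @param df Degrees of freedom (integer \eqn{\ge 1}) for \code{t_density};
#'   the default 30 is the usual large-sample choice.
#' @param c Positive scale for \code{multiscale_t}.
#' @param on_squared_distance Apply the multi-scale t form to the squared
#'   distance instead of the distance.
#' @param degree,offset Degree (integer \eqn{\ge 1}) and offset of the
#'   \code{polynomial} kernel \eqn{(\langle x,y\rangle + b)^q}; \code{offset}
#'   is also the intercept of the \code{tanh} kernel.
#' @param slope Slope of the \code{tanh} kernel
#'   \eqn{\tanh(a\langle x,y\rangle + b)}.
#' @return An object of class \code{"kernel_spec"} with fields \code{family},
#'   \code{params} and \code{arg_kind} (\code{"distance"} or
#'   \code{"inner_product"}).
#' @examples
#' kernel_spec("gaussian", gamma = 0.1)
#' kernel_spec("multiscale_t", c = 0.1, on_squared_distance = TRUE)
#' @export
kernel_spec <- function(family = c("gaussian", "laplace", "t_density", "cauchy",
                                   "pseudo_t", "multiscale_t", "linear",
                                   "polynomial", "tanh"),
                        gamma = 0.1, df = 30, c = 0.2,
                        on_squared_distance = FALSE,
                        degree = 1L, offset = 0, slope = 1) {
  family <- match.arg(family)
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("kernel parameter '%s' must be a positive finite scalar", nm),
           call. = FALSE)
  }
  params <- switch(family,
    gaussian = , laplace = { check_pos(gamma, "gamma"); list(gamma = gamma) },
    t_density = {
      if (!is.numeric(df) || length(df) != 1L || !is.finite(df) ||
          df < 1 || df != round(df))
        stop("kernel parameter 'df' must be an integer >= 1", call. = FALSE)
      list(df = as.integer(df))
    },
    cauchy = , pseudo_t = list(),
    multiscale_t = {
      check_pos(c, "c")
      list(c = c, on_squared_distance = isTRUE(on_squared_distance))
    },
    linear = list(),
    polynomial = {
      if (!is.numeric(degree) || length(degree) != 1L || degree < 1 ||
          degree != round(degree))
        stop("kernel parameter 'degree' must be an integer >= 1", call. = FALSE)
      list(degree = as.integer(degree), offset = offset)
    },
    tanh = list(slope = slope, offset = offset)
  )
  arg_kind <- if (family %in% c("linear", "polynomial", "tanh"))
    "inner_product" else "distance"
  structure(list(family = family, params = params, arg_kind = arg_kind),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  ps <- if (length(x$params) == 0L) "" else
    paste0("(", paste(names(x$params), unlist(x$params), sep = " = ",
                      collapse = ", "), ")")
  cat("kernel: ", x$family, ps, " on ", gsub("_", " ", x$arg_kind), "\n",
      sep = "")
  invisible(x)
}

#' Kernel presets used for weighted combinations
#'
#' Named preset lists of kernel specifications for the published
#' combinations: \code{"eq33"} combines the multi-scale t kernel on the
#' squared distance (scale \code{c1}) with the multi-scale t kernel on the
#' distance (scale \code{c2}); \code{"eq34"} adds a Gaussian kernel in front;
#' \code{"eq35"} uses a Laplace kernel in front instead; \code{"gaussian"}
#' (alias \code{"eq36"}) is the single Gaussian kernel used as the
#' single-kernel baseline. Defaults \code{c1 = 0.1}, \code{c2 = 0.2},
#' \code{gamma = 0.1} follow the wrapper-selected values of the original
#' study.
#'
#' @param name Preset name.
#' @param c1,c2,gamma Scale parameters, overriding the defaults.
#' @return A list of \code{\link{kernel_spec}} objects.
#' @examples
#' kernel_preset("eq34")
#' @export
kernel_preset <- function(name = c("eq33", "eq34", "eq35", "gaussian", "eq36"),
                          c1 = 0.1, c2 = 0.2, gamma = 0.1) {
  name <- match.arg(name)
  ms <- list(kernel_spec("multiscale_t", c = c1, on_squared_distance = TRUE),
             kernel_spec("multiscale_t", c = c2))
  switch(name,
    eq33 = ms,
    eq34 = c(list(kernel_spec("gaussian", gamma = gamma)), ms),
    eq35 = c(list(kernel_spec("laplace", gamma = gamma)), ms),
    gaussian = , eq36 = list(kernel_spec("gaussian", gamma = gamma)))
}

check_finite_rows <- function(X, what = "input matrix") {
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s contains non-finite values (first offending row: %d)",
                 what, bad[1L, 1L]), call. = FALSE)
  invisible(TRUE)
}

as_data_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("expected a numeric matrix of samples x features", call. = FALSE)
  X
}

#' Pairwise Euclidean distance matrix
#'
#' @param X Numeric samples-by-features matrix.
#' @return Symmetric nonnegative m x m matrix with zero diagonal; entry
#'   (i, j) is \eqn{\|x_i - x_j\|}.
#' @examples
#' pairwise_distance_matrix(rbind(c(0, 0), c(3, 4)))
#' @export
pairwise_distance_matrix <- function(X) {
  X <- as_data_matrix(X)
  check_finite_rows(X)
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(D) <- NULL
  diag(D) <- 0
  D
}

# cross-block distances between two sample sets (rows of A vs rows of B)
cross_distance_matrix <- function(A, B) {
  A <- as_data_matrix(A); B <- as_data_matrix(B)
  if (ncol(A) != ncol(B))
    stop("feature counts differ between the two sample sets", call. = FALSE)
  check_finite_rows(A); check_finite_rows(B)
  # explicit differences, one vectorized sweep per row of A: the expanded
  # inner-product formula loses ~sqrt(eps) of precision near zero distance,
  # which matters when a new sample duplicates a training sample
  tB <- t(B)
  D <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    D[i, ] <- sqrt(colSums((tB - A[i, ])^2))
  D
}

#' Pairwise inner-product (Gram) matrix
#'
#' @param X Numeric samples-by-features matrix.
#' @return Symmetric m x m matrix \eqn{X X^\top}.
#' @export
inner_product_matrix <- function(X) {
  X <- as_data_matrix(X)
  check_finite_rows(X)
  G <- tcrossprod(X)
  dimnames(G) <- NULL
  G
}

#' Evaluate a kernel function on scalar arguments
#'
#' Applies the kernel named by \code{spec} to \code{arg}, elementwise.
#' Distance families take the Euclidean distance (nonnegative); inner-product
#' families take the inner product (any real).
#'
#' @param spec A \code{\link{kernel_spec}}.
#' @param arg Numeric scalar, vector or matrix of arguments.
#' @return Kernel values with the shape of \code{arg}.
#' @examples
#' kernel_value(kernel_spec("cauchy"), 1)       # 1 / (2 * pi)
#' kernel_value(kernel_spec("multiscale_t", c = 0.2), 0)  # 5
#' @export
kernel_value <- function(spec, arg) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.numeric(arg) || anyNA(arg) || any(!is.finite(arg)))
    stop("kernel argument must be finite numeric", call. = FALSE)
  if (spec$arg_kind == "distance" && any(arg < 0))
    stop(sprintf("negative argument passed to distance-based kernel '%s'",
                 spec$family), call. = FALSE)
  p <- spec$params
  out <- switch(spec$family,
    gaussian = exp(-p$gamma * arg^2),
    laplace = exp(-p$gamma * arg),
    t_density = {
      n <- p$df
      cn <- exp(lgamma((n + 1) / 2) - lgamma(n / 2)) / sqrt(n * pi)
      cn * (1 + arg^2 / n)^(-(n + 1) / 2)
    },
    cauchy = 1 / (pi * (1 + arg^2)),
    pseudo_t = 1 / (pi * (1 + arg)),
    multiscale_t = if (isTRUE(p$on_squared_distance))
      1 / (p$c * (1 + arg^2)) else 1 / (p$c * (1 + arg)),
    linear = arg,
    polynomial = (arg + p$offset)^p$degree,
    tanh = tanh(p$slope * arg + p$offset))
  out
}

#' Build the Gram matrix of a kernel
#'
#' The kernel is applied elementwise to the whole distance or inner-product
#' matrix (vectorized), never in a per-pair scalar loop.
#'
#' @param spec A \code{\link{kernel_spec}}.
#' @param X Samples-by-features matrix (may be omitted when
#'   \code{precomputed} is given).
#' @param precomputed Optional precomputed m x m distance or inner-product
#'   matrix matching the spec's argument kind.
#' @return m x m kernel matrix with attribute \code{"spec"}.
#' @examples
#' kernel_matrix(kernel_spec("gaussian", gamma = 0.1), rbind(c(0, 0), c(3, 4)))
#' @export
kernel_matrix <- function(spec, X = NULL, precomputed = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (is.null(precomputed)) {
    if (is.null(X)) stop("either X or precomputed must be supplied",
                         call. = FALSE)
    precomputed <- if (spec$arg_kind == "distance")
      pairwise_distance_matrix(X) else inner_product_matrix(X)
  } else {
    if (!is.matrix(precomputed) || nrow(precomputed) != ncol(precomputed))
      stop("precomputed argument matrix must be square", call. = FALSE)
    if (!is.null(X) && nrow(as_data_matrix(X)) != nrow(precomputed))
      stop("precomputed matrix shape does not match X", call. = FALSE)
  }
  K <- kernel_value(spec, precomputed)
  attr(K, "spec") <- spec
  K
}

#' Convex combination of kernel matrices
#'
#' Builds \eqn{K = \sum_s \omega_s K_s} from per-kernel Gram matrices on the
#' same samples. Weights must be nonnegative and sum to one; any convex
#' combination of positive semi-definite Gram matrices is again a valid
#' kernel matrix.
#'
#' @param specs List of \code{\link{kernel_spec}} objects.
#' @param weights Numeric vector of the same length, nonnegative, summing
#'   to 1 (within 1e-9).
#' @param X Samples-by-features matrix (optional when \code{precomputed}
#'   supplies every Gram argument).
#' @param precomputed Optional named list with elements \code{distance}
#'   and/or \code{inner_product}, shared across specs.
#' @return The weighted m x m kernel matrix with attributes \code{"specs"}
#'   and \code{"weights"}.
#' @export
weighted_kernel_matrix <- function(specs, weights, X = NULL,
                                   precomputed = NULL) {
  if (inherits(specs, "kernel_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop("at least one kernel spec required",
                                call. = FALSE)
  if (length(weights) != length(specs))
    stop("weights and specs must have the same length", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("invalid weights: must be nonnegative and sum to 1", call. = FALSE)
  mats <- shared_argument_matrices(specs, X, precomputed)
  K <- 0
  for (s in seq_along(specs)) {
    arg <- mats[[specs[[s]]$arg_kind]]
    K <- K + weights[s] * kernel_value(specs[[s]], arg)
  }
  attr(K, "specs") <- specs
  attr(K, "weights") <- weights
  K
}

# compute each required argument matrix (distance / inner product) once
shared_argument_matrices <- function(specs, X = NULL, precomputed = NULL) {
  kinds <- unique(vapply(specs, `[[`, "", "arg_kind"))
  out <- list()
  for (kind in kinds) {
    key <- if (kind == "distance") "distance" else "inner_product"
    if (!is.null(precomputed) && !is.null(precomputed[[key]])) {
      M <- precomputed[[key]]
      if (!is.matrix(M) || nrow(M) != ncol(M))
        stop(sprintf("precomputed %s matrix must be square", key),
             call. = FALSE)
      out[[key]] <- M
    } else {
      if (is.null(X))
        stop(sprintf("no data and no precomputed %s matrix supplied", key),
             call. = FALSE)
      out[[key]] <- if (kind == "distance")
        pairwise_distance_matrix(X) else inner_product_matrix(X)
    }
  }
  out
}

#' Smallest eigenvalue of a symmetric matrix
#'
#' Used to test positive semi-definiteness of kernel matrices numerically:
#' a valid kernel matrix satisfies \code{min_eigenvalue(K) >= -tol * trace}.
#'
#' @param K Symmetric numeric matrix.
#' @return The smallest eigenvalue of \code{(K + t(K)) / 2}.
#' @export
min_eigenvalue <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("K must be a square matrix", call. = FALSE)
  if (any(!is.finite(K)))
    stop("K contains non-finite entries", call. = FALSE)
  min(eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
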