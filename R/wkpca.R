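#' Eigendecomposition of a kernel matrix
#'
#' @param K Symmetric kernel matrix.
#' @return List with \code{values} (eigenvalues, nonincreasing) and
#'   \code{vectors} (orthonormal columns, column j pairing with value j).
#' @export
eigendecompose_kernel <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("K must be a square matrix", call. = FALSE)
  if (any(!is.finite(K)))
    stop("K contains non-finite entries", call. = FALSE)
  e <- tryCatch(eigen((K + t(K)) / 2, symmetric = TRUE),
                error = function(err)
                  stop(sprintf(
                    "eigendecomposition failed (m = %d, max |K| = %g): %s",
                    nrow(K), max(abs(K)), conditionMessage(err)),
                    call. = FALSE))
  list(values = e$values, vectors = e$vectors)
}

# negative / numerically-zero eigenvalues are clamped to 0 before they enter
# weights, efficiencies or dimension selection; |lambda| <= 1e-10 * lambda_1
# counts as zero
clamp_spectrum <- function(lambda) {
  if (length(lambda) == 0L) return(lambda)
  tol <- 1e-10 * max(lambda, 0)
  lambda[lambda <= tol] <- 0
  lambda
}

#' Eigenvalue-ratio kernel weights
#'
#' The weight of kernel \eqn{i} is the sum of its leading \eqn{d}
#' eigenvalues divided by the same sum taken over all kernels:
#' \eqn{\omega_i = \sum_{j \le d} \lambda_j^i / \sum_i \sum_{j \le d}
#' \lambda_j^i}. Negative eigenvalues (floating-point artefacts) are clamped
#' to zero first.
#'
#' @param spectra List of per-kernel eigenvalue vectors, each sorted
#'   nonincreasing with length \eqn{\ge d}.
#' @param d Number of leading eigenvalues entering each partial sum.
#' @return Weight vector on the simplex (nonnegative, summing to 1).
#' @examples
#' compute_kernel_weights(list(c(4, 2, 1), c(2, 1, 1)), d = 2)  # 2/3, 1/3
#' @export
compute_kernel_weights <- function(spectra, d) {
  if (!is.list(spectra) || length(spectra) == 0L)
    stop("spectra must be a nonempty list of eigenvalue vectors",
         call. = FALSE)
  d <- as.integer(d)
  if (d < 1L || any(vapply(spectra, length, 1L) < d))
    stop("d must satisfy 1 <= d <= length of every spectrum", call. = FALSE)
  partial <- vapply(spectra, function(l) sum(clamp_spectrum(l)[seq_len(d)]),
                    numeric(1))
  total <- sum(partial)
  if (total <= 0)
    stop("degenerate spectra: all leading eigenvalue sums are zero",
         call. = FALSE)
  partial / total
}

#' Cumulative dimension-reduction efficiency
#'
#' The fraction of the (clamped) spectrum captured by the leading \eqn{d}
#' components, \eqn{R_d = \sum_{j \le d}\lambda_j / \sum_{j \le m}\lambda_j}.
#'
#' @param lambda Eigenvalues sorted nonincreasing.
#' @param d Number of leading components, \eqn{1 \le d \le m}.
#' @return \eqn{R_d} in \eqn{[0, 1]}; \eqn{R_m = 1}.
#' @export
cumulative_efficiency <- function(lambda, d) {
  lambda <- clamp_spectrum(lambda)
  d <- as.integer(d)
  if (d < 1L || d > length(lambda))
    stop("d must satisfy 1 <= d <= length(lambda)", call. = FALSE)
  total <- sum(lambda)
  if (total <= 0)
    stop("degenerate spectrum: all eigenvalues are zero", call. = FALSE)
  sum(lambda[seq_len(d)]) / total
}

#' Choose the retained dimension from a spectrum
#'
#' Returns the smallest \eqn{d} whose cumulative efficiency reaches
#' \code{threshold}. The customary band for the threshold is 0.8--0.9;
#' the default is 0.8.
#'
#' @param lambda Eigenvalues sorted nonincreasing.
#' @param threshold Target cumulative efficiency in (0, 1].
#' @return The smallest \eqn{d} with \eqn{R_d \ge} \code{threshold}.
#' @export
select_dimension <- function(lambda, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  lambda <- clamp_spectrum(lambda)
  total <- sum(lambda)
  if (total <= 0)
    stop("degenerate spectrum: all eigenvalues are zero", call. = FALSE)
  which(cumsum(lambda) / total >= threshold - 1e-12)[1L]
}

# double-center a Gram matrix: H K H with H = I - 11'/m
center_gram <- function(K) {
  cm <- colMeans(K)
  K - outer(rep(1, nrow(K)), cm) - outer(rowMeans(K), rep(1, ncol(K))) +
    mean(K)
}

#' Fit a weighted-kernel principal component model
#'
#' Fits the weighted-kernel PCA reducer: each kernel's Gram matrix is built
#' from a shared distance and/or inner-product matrix, per-kernel eigenvalue
#' spectra give combination weights proportional to their leading partial
#' sums, the weighted Gram matrix is eigendecomposed, and samples are
#' projected onto its leading \eqn{d} eigenvectors.
#'
#' When \code{d} is \code{NULL} the retained dimension is chosen
#' automatically: for each candidate \eqn{d = 1, 2, \ldots} the weights and
#' the weighted spectrum are recomputed (the weights depend on \eqn{d}) and
#' the smallest \eqn{d} whose cumulative efficiency reaches
#' \code{threshold} is kept.
#'
#' Centering of the Gram matrix is off by default, matching the original
#' formulation; \code{centered = TRUE} applies the standard double-centering,
#' under which a linear kernel reproduces classical PCA (see
#' \code{alpha_scaling = "feature_space"}).
#'
#' @param x Numeric samples-by-features matrix (rows are samples).
#' @param kernels A \code{\link{kernel_spec}}, a list of them, or a preset
#'   name accepted by \code{\link{kernel_preset}}.
#' @param d Retained dimension, or \code{NULL} to select it from the
#'   cumulative efficiency threshold.
#' @param threshold Cumulative-efficiency target used when \code{d} is
#'   \code{NULL} (and reported regardless).
#' @param centered Double-center the Gram matrices before decomposition.
#' @param alpha_scaling \code{"unit"} keeps eigenvectors at unit Euclidean
#'   norm (the literal reading of the algorithm); \code{"feature_space"}
#'   rescales column \eqn{j} so \eqn{\lambda_j \|\alpha^j\|^2 = 1}, the
#'   normalization under which projections coincide with coordinates in the
#'   implicit feature space (and with classical PCA for a centered linear
#'   kernel).
#' @return An object of class \code{"wkpca"} with components \code{weights}
#'   (kernel weights), \code{lambda} (weighted-Gram eigenvalues),
#'   \code{alpha} (scaled eigenvectors), \code{d}, \code{scores} (training
#'   embedding, m x d) and the retained training data. Use
#'   \code{\link{predict.wkpca}} to embed new samples.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 6), 40)
#' fit <- wkpca(x, kernels = "eq34", threshold = 0.8)
#' fit
#' head(predict(fit, x[1:3, , drop = FALSE]))
#' @export
wkpca <- function(x, kernels = "eq34", d = NULL, threshold = 0.8,
                  centered = FALSE,
                  alpha_scaling = c("unit", "feature_space")) {
  alpha_scaling <- match.arg(alpha_scaling)
  x <- as_data_matrix(x)
  check_finite_rows(x)
  m <- nrow(x)
  if (m < 2L) stop("at least two samples are required to fit", call. = FALSE)
  if (is.character(kernels)) kernels <- kernel_preset(kernels)
  if (inherits(kernels, "kernel_spec")) kernels <- list(kernels)
  if (!is.list(kernels) || length(kernels) == 0L ||
      !all(vapply(kernels, inherits, TRUE, "kernel_spec")))
    stop("kernels must be kernel_spec objects or a preset name",
         call. = FALSE)

  mats <- shared_argument_matrices(kernels, x)
  grams_raw <- lapply(kernels, function(sp)
    kernel_value(sp, mats[[sp$arg_kind]]))
  grams <- if (centered) lapply(grams_raw, center_gram) else grams_raw
  spectra <- lapply(grams, function(K)
    eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)

  combine <- function(w, gs = grams) {
    K <- 0
    for (s in seq_along(gs)) K <- K + w[s] * gs[[s]]
    K
  }

  if (!is.null(d)) {
    d <- as.integer(d)
    if (d < 1L || d > m)
      stop(sprintf("d must satisfy 1 <= d <= m = %d", m), call. = FALSE)
    w <- compute_kernel_weights(spectra, d)
    eig <- eigendecompose_kernel(combine(w))
  } else {
    for (dd in seq_len(m)) {
      w <- compute_kernel_weights(spectra, dd)
      eig <- eigendecompose_kernel(combine(w))
      if (cumulative_efficiency(eig$values, dd) >= threshold) { d <- dd; break }
    }
  }

  lambda <- eig$values
  alpha <- eig$vectors
  if (alpha_scaling == "feature_space") {
    lam <- clamp_spectrum(lambda)
    pos <- lam > 0
    if (any(pos))
      alpha[, pos] <- sweep(alpha[, pos, drop = FALSE], 2,
                            sqrt(lam[pos]), `/`)
    if (d > sum(pos))
      stop("feature_space scaling needs d positive eigenvalues", call. = FALSE)
  }
  # raw (uncentered) weighted Gram statistics are what centering of a new
  # sample's cross-kernel block needs
  Kw_raw <- combine(w, grams_raw)
  scores <- combine(w) %*% alpha[, seq_len(d), drop = FALSE]
  colnames(scores) <- paste0("KPC", seq_len(d))
  rownames(scores) <- rownames(x)

  structure(list(
    x = x, kernels = kernels, weights = w, lambda = lambda,
    lambda_by_kernel = spectra, alpha = alpha, d = d,
    threshold = threshold, centered = centered,
    alpha_scaling = alpha_scaling, scores = scores,
    gram_col_means = colMeans(Kw_raw), gram_mean = mean(Kw_raw)),
    class = "wkpca")
}

#' Project samples with a fitted weighted-kernel PCA model
#'
#' Embeds new samples by evaluating the fitted weighted kernel between each
#' new sample and every training sample (one vectorized cross-kernel block)
#' and contracting with the stored eigenvector coefficients:
#' \eqn{z_j(x) = \sum_i \alpha_{ij}\, \kappa_w(x_i, x)}.
#'
#' @param object A fitted \code{\link{wkpca}} model.
#' @param newdata Samples-by-features matrix with the training feature
#'   count; omitted, the training embedding is returned.
#' @param ... Unused.
#' @return Numeric matrix with one row per sample and \code{object$d}
#'   columns.
#' @export
predict.wkpca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  newdata <- as_data_matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop(sprintf("newdata has %d features; model was fitted with %d",
                 ncol(newdata), ncol(object$x)), call. = FALSE)
  check_finite_rows(newdata, "newdata")
  kinds <- unique(vapply(object$kernels, `[[`, "", "arg_kind"))
  cross <- list()
  if ("distance" %in% kinds)
    cross$distance <- cross_distance_matrix(newdata, object$x)
  if ("inner_product" %in% kinds)
    cross$inner_product <- tcrossprod(newdata, object$x)
  K <- 0
  for (s in seq_along(object$kernels)) {
    sp <- object$kernels[[s]]
    K <- K + object$weights[s] * kernel_value(sp, cross[[sp$arg_kind]])
  }
  if (object$centered) {
    m <- nrow(object$x)
    K <- K - outer(rowMeans(K), rep(1, m)) -
      outer(rep(1, nrow(K)), object$gram_col_means) + object$gram_mean
  }
  scores <- K %*% object$alpha[, seq_len(object$d), drop = FALSE]
  colnames(scores) <- paste0("KPC", seq_len(object$d))
  rownames(scores) <- rownames(newdata)
  scores
}

#' @export
print.wkpca <- function(x, ...) {
  cat(sprintf(
    "Weighted kernel PCA: %d samples x %d features -> %d components\n",
    nrow(x$x), ncol(x$x), x$d))
  fams <- vapply(x$kernels, `[[`, "", "family")
  cat("kernels and weights:\n")
  for (s in seq_along(fams))
    cat(sprintf("  %-14s w = %.4f\n", fams[s], x$weights[s]))
  cat(sprintf("cumulative efficiency R_d = %.4f (threshold %.2f)%s\n",
              cumulative_efficiency(x$lambda, x$d), x$threshold,
              if (x$centered) ", centered Gram" else ""))
  invisible(x)
}

#' @export
summary.wkpca <- function(object, ...) {
  lam <- clamp_spectrum(object$lambda)
  eff <- cumsum(lam) / sum(lam)
  out <- list(
    m = nrow(object$x), p = ncol(object$x), d = object$d,
    kernels = vapply(object$kernels, `[[`, "", "family"),
    weights = object$weights,
    efficiency = eff[seq_len(min(length(eff), max(object$d, 10L)))],
    threshold = object$threshold, centered = object$centered,
    min_eigenvalue = min(object$lambda))
  class(out) <- "summary.wkpca"
  out
}

#' @export
print.summary.wkpca <- function(x, ...) {
  cat(sprintf("Weighted kernel PCA fit: m = %d, p = %d, d = %d\n",
              x$m, x$p, x$d))
  cat("kernel weights:", sprintf("%.4f", x$weights), "\n")
  cat("cumulative efficiency of leading components:\n")
  print(round(x$efficiency, 4))
  cat(sprintf("smallest raw eigenvalue: %.3e\n", x$min_eigenvalue))
  invisible(x)
}

#' Kernel combination weights of a fitted model
#'
#' @param object A fitted \code{\link{wkpca}} model.
#' @param ... Unused.
#' @return Numeric vector of kernel weights (nonnegative, summing to 1).
#' @export
weights.wkpca <- function(object, ...) object$weights

#' Plot a weighted-kernel PCA embedding
#'
#' Scatterplot of two embedding coordinates of the training samples.
#'
#' @param x A fitted \code{\link{wkpca}} model.
#' @param dims Two component indices to display.
#' @param labels Optional class labels used to colour points.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.wkpca <- function(x, dims = c(1L, 2L), labels = NULL, ...) {
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 1L) || any(dims > x$d))
    stop("dims must name two fitted components", call. = FALSE)
  s <- x$scores[, dims, drop = FALSE]
  col <- if (is.null(labels)) 1L else as.integer(factor(labels))
  graphics::plot(s[, 1L], s[, 2L], col = col, pch = 19,
                 xlab = colnames(s)[1L], ylab = colnames(s)[2L], ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))), pch = 19,
                     bty = "n")
  invisible(x)
}
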