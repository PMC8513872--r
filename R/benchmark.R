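#' Load a benchmark results table
#'
#' Reads a results grid in tidy or wide form. The packaged default is the
#' transcription of the published comparison of five classifiers (NB, SVM,
#' KNN, RF, IRF) by four reduction strategies (AV, PCA, SKPCA, WKPCA) on six
#' Broad Institute expression datasets, four metrics per cell (see the
#' comment header of the CSV for transcription notes). Wide tables with one
#' column per metric are pivoted to long form.
#'
#' @param path CSV file; \code{NULL} loads the packaged transcription.
#' @return A data frame of class \code{"results_table"} with columns
#'   \code{dataset}, \code{classifier}, \code{strategy}, \code{metric},
#'   \code{value} (plus any extras such as \code{n_features}).
#' @export
load_results_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "broad_tables_metrics.csv",
                        package = "wkpca", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  as_results_table(tab)
}

#' Coerce a data frame to a results table
#'
#' @param tab Data frame with \code{dataset}, \code{classifier},
#'   \code{strategy} columns and either \code{metric}/\code{value} columns
#'   (long form) or one numeric column per metric (wide form).
#' @return A \code{"results_table"} data frame in long form.
#' @export
as_results_table <- function(tab) {
  need <- c("dataset", "classifier", "strategy")
  if (!all(need %in% names(tab)))
    stop("results table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("metric", "value") %in% names(tab))) {
    metric_cols <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)],
                           c("n_features", "seed"))
    if (length(metric_cols) == 0L)
      stop("no metric columns found in results table", call. = FALSE)
    keep <- intersect(names(tab), c(need, "n_features"))
    long <- do.call(rbind, lapply(metric_cols, function(mc) {
      out <- tab[keep]
      out$metric <- mc
      out$value <- tab[[mc]]
      out
    }))
    tab <- long
  }
  rownames(tab) <- NULL
  class(tab) <- c("results_table", "data.frame")
  tab
}

# split into (classifier, dataset, metric) cells, verifying completeness
results_cells <- function(results, target) {
  stopifnot(is.data.frame(results))
  strategies <- unique(results$strategy)
  if (!target %in% strategies)
    stop(sprintf("strategy '%s' absent from results table", target),
         call. = FALSE)
  key <- interaction(results$classifier, results$dataset, results$metric,
                     drop = TRUE, sep = " / ")
  cells <- split(results, key)
  bad <- names(cells)[vapply(cells, function(cell)
    !setequal(cell$strategy, strategies) ||
      nrow(cell) != length(strategies), TRUE)]
  if (length(bad))
    stop("incomplete results grid; offending cells: ",
         paste(utils::head(bad, 10L), collapse = "; "), call. = FALSE)
  cells
}

#' Optimal performance rate
#'
#' The fraction of (classifier, dataset, metric) cells in which the target
#' reduction strategy attains the maximum value over all strategies, ties
#' counting as attained: \eqn{OPR = PN / (MN \times DN \times EN)}. Cells
#' where the target's value is missing count as not attained; missing
#' competitor values are ignored.
#'
#' @param results A \code{"results_table"} (see
#'   \code{\link{load_results_table}}).
#' @param target Strategy whose optimality is counted.
#' @return The rate, a number in \eqn{[0, 1]}, with attributes
#'   \code{attained}, \code{cells} and \code{misses_by_dataset}.
#' @examples
#' opr(load_results_table())
#' @export
opr <- function(results, target = "WKPCA") {
  cells <- results_cells(results, target)
  attained <- vapply(cells, function(cell) {
    v <- cell$value[cell$strategy == target]
    !is.na(v) && v >= max(cell$value, na.rm = TRUE)
  }, TRUE)
  miss <- vapply(cells[!attained], function(cell) cell$dataset[1L], "")
  rate <- mean(attained)
  attr(rate, "attained") <- sum(attained)
  attr(rate, "cells") <- length(attained)
  attr(rate, "misses_by_dataset") <- if (length(miss)) table(miss) else
    table(character())
  rate
}

#' Cumulative optimal performance rate
#'
#' Counts, for each rank \eqn{i}, the cells in which the target strategy
#' holds the \eqn{i}-th largest value (ties share the better rank), and
#' accumulates ranks \eqn{1, \ldots, s + 1}:
#' \eqn{COPR = \sum_{i \le s+1} PN_i / (MN \times DN \times EN)}. With
#' \code{s = 0} this is exactly \code{\link{opr}}.
#'
#' @inheritParams opr
#' @param s Rank depth: how many runner-up positions beyond first count.
#' @return The cumulative rate with attribute \code{rank_counts}
#'   (\eqn{PN_1, PN_2, \ldots}).
#' @export
copr <- function(results, s = 1L, target = "WKPCA") {
  s <- as.integer(s)
  if (s < 0L) stop("rank depth s must be >= 0", call. = FALSE)
  cells <- results_cells(results, target)
  nstrat <- length(unique(results$strategy))
  ranks <- vapply(cells, function(cell) {
    v <- cell$value[cell$strategy == target]
    if (is.na(v)) return(NA_integer_)
    others <- cell$value[cell$strategy != target]
    1L + sum(others > v, na.rm = TRUE)  # ties share the better rank
  }, 1L)
  counts <- vapply(seq_len(nstrat), function(i)
    sum(ranks == i, na.rm = TRUE), 1L)
  names(counts) <- paste0("PN", seq_len(nstrat))
  rate <- sum(counts[seq_len(min(s + 1L, nstrat))]) / length(cells)
  attr(rate, "rank_counts") <- counts
  attr(rate, "cells") <- length(cells)
  rate
}

## ---- classifiers ---------------------------------------------------------

# uniform train/predict contract: fit_classifier returns an object for which
# predict_classifier gives list(class = factor, prob = matrix or NULL)
fit_classifier <- function(id, x, y, params = list()) {
  x <- as.matrix(x)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("degenerate training fold: single class present", call. = FALSE)
  model <- switch(id,
    nb = e1071::naiveBayes(x, y),
    svm = e1071::svm(x, y, kernel = "radial",
                     gamma = params$gamma %||% (1 / ncol(x)),
                     cost = params$cost %||% 1, probability = TRUE),
    knn = caret::knn3(x, y, k = params$k %||% 5L),
    rf = randomForest::randomForest(x, y,
                                    ntree = params$ntree %||% 500L),
    irf = fit_irf(x, y, ntree = params$ntree %||% 500L,
                  iterations = params$iterations %||% 6L),
    majority = {
      tab <- table(y)
      list(level = names(tab)[which.max(tab)], levels = levels(y),
           freq = as.numeric(tab) / length(y))
    },
    stop("unknown classifier id: ", id, call. = FALSE))
  structure(list(id = id, model = model, levels = levels(y)),
            class = "wkpca_classifier")
}

predict_classifier <- function(fit, xnew) {
  xnew <- as.matrix(xnew)
  colnames(xnew) <- paste0("V", seq_len(ncol(xnew)))
  id <- fit$id; model <- fit$model
  if (id == "nb") {
    prob <- stats::predict(model, xnew, type = "raw")
    cls <- colnames(prob)[max.col(prob, ties.method = "first")]
  } else if (id == "svm") {
    pred <- stats::predict(model, xnew, probability = TRUE)
    prob <- attr(pred, "probabilities")
    prob <- prob[, order(colnames(prob)), drop = FALSE]
    cls <- as.character(pred)
  } else if (id == "knn") {
    prob <- stats::predict(model, xnew, type = "prob")
    cls <- colnames(prob)[max.col(prob, ties.method = "first")]
  } else if (id == "rf") {
    prob <- stats::predict(model, xnew, type = "prob")
    cls <- as.character(stats::predict(model, xnew, type = "response"))
  } else if (id == "irf") {
    xw <- sweep(xnew, 2, model$feature_weights, `*`)
    prob <- stats::predict(model$forest, xw, type = "prob")
    cls <- as.character(stats::predict(model$forest, xw,
                                       type = "response"))
  } else if (id == "majority") {
    prob <- matrix(model$freq, nrow(xnew), length(model$levels),
                   byrow = TRUE, dimnames = list(NULL, model$levels))
    cls <- rep(model$level, nrow(xnew))
  }
  list(class = factor(cls, levels = fit$levels), prob = prob)
}

# iterative random forest: refit with features rescaled by normalized
# importance from the previous iteration
fit_irf <- function(x, y, ntree = 500L, iterations = 6L) {
  w <- rep(1, ncol(x))
  forest <- NULL
  for (it in seq_len(iterations)) {
    xw <- sweep(x, 2, w, `*`)
    forest <- randomForest::randomForest(xw, y, ntree = ntree)
    imp <- randomForest::importance(forest)[, 1L]
    imp <- pmax(imp, 0)
    if (sum(imp) == 0) break
    w <- w * imp / mean(imp)
    if (max(w) > 0) w <- w / max(w)
  }
  list(forest = forest, feature_weights = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- cross-validation ----------------------------------------------------

# deterministic 31-bit string hash, for deriving per-task seeds from names
string_seed <- function(...) {
  s <- paste(..., collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# stratified fold assignment; folds shrink (with a warning) when the
# smallest class has fewer members than requested folds
stratified_folds <- function(y, nfolds, seed) {
  y <- factor(y)
  smallest <- min(table(y))
  if (smallest < 2L)
    stop("configuration error: a class has fewer than 2 members",
         call. = FALSE)
  if (smallest < nfolds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    nfolds, smallest), call. = FALSE)
    nfolds <- smallest
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

#' Experiment configuration
#'
#' Collects the settings of a comparison run: reduction strategies, the
#' kernel combination used by WKPCA, classifier hyperparameter grids
#' (defaults follow the published protocol: SVM gamma searched over 0.1 to 4
#' in steps of 0.1, k-NN neighbours over 1 to 30; random forest fixed at 500
#' trees; iterative random forest at 6 refit iterations), fold counts for
#' the nested cross-validation, the dimension policy and the master seed.
#'
#' @param strategies Reduction strategies to compare.
#' @param classifiers Classifier identifiers among \code{"nb"},
#'   \code{"svm"}, \code{"knn"}, \code{"rf"}, \code{"irf"} (and
#'   \code{"majority"}, a baseline that always predicts the modal class).
#' @param kernels Kernel preset name or list of \code{\link{kernel_spec}}
#'   for the WKPCA strategy.
#' @param folds,inner_folds Outer and inner stratified fold counts
#'   (\eqn{\ge 2}).
#' @param d Explicit retained dimension, or \code{NULL} to use
#'   \code{threshold}.
#' @param threshold Cumulative-efficiency target for automatic dimension
#'   selection.
#' @param grids Named list of per-classifier hyperparameter grids; each grid
#'   is a named list of candidate vectors, expanded factorially.
#' @param transductive Fit the reduction on the full dataset before
#'   splitting (reproducibility escape hatch); the default fits it inside
#'   each outer training fold, which is leakage-free.
#' @param seed Master seed; all fold and tuning randomness derives from it.
#' @return A list of class \code{"experiment_config"}.
#' @export
experiment_config <- function(strategies = c("AV", "PCA", "SKPCA", "WKPCA"),
                              classifiers = c("nb", "svm", "knn", "rf",
                                              "irf"),
                              kernels = "eq34",
                              folds = 5L, inner_folds = 5L,
                              d = NULL, threshold = 0.8,
                              grids = default_grids(),
                              transductive = FALSE, seed = 1L) {
  folds <- as.integer(folds); inner_folds <- as.integer(inner_folds)
  if (folds < 2L || inner_folds < 2L)
    stop("fold counts must be >= 2", call. = FALSE)
  structure(list(strategies = strategies, classifiers = classifiers,
                 kernels = kernels, folds = folds,
                 inner_folds = inner_folds, d = d, threshold = threshold,
                 grids = grids, transductive = isTRUE(transductive),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Default hyperparameter grids
#'
#' @return Named list of per-classifier grids: SVM gamma 0.1--4 by 0.1,
#'   k-NN k = 1--30; the tree ensembles use fixed settings (500 trees,
#'   6 refit iterations) and need no search.
#' @export
default_grids <- function() {
  list(svm = list(gamma = seq(0.1, 4, by = 0.1)),
       knn = list(k = 1:30))
}

# fit the reduction on the training block, apply to both blocks
apply_reduction <- function(strategy, xtrain, xtest, config) {
  if (strategy == "AV")
    return(list(train = xtrain, test = xtest, d = ncol(xtrain)))
  if (strategy == "PCA") {
    pc <- stats::prcomp(xtrain, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    d <- if (!is.null(config$d)) min(config$d, ncol(pc$x)) else
      select_dimension(ev, config$threshold)
    return(list(train = pc$x[, seq_len(d), drop = FALSE],
                test = stats::predict(pc, xtest)[, seq_len(d),
                                                 drop = FALSE],
                d = d))
  }
  kernels <- if (strategy == "SKPCA") "gaussian" else config$kernels
  fit <- wkpca(xtrain, kernels = kernels, d = config$d,
               threshold = config$threshold)
  list(train = fit$scores, test = predict(fit, xtest), d = fit$d)
}

# factorial grid expansion -> list of parameter lists
expand_grid_list <- function(grid) {
  if (is.null(grid) || length(grid) == 0L) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# inner-CV grid search maximizing accuracy; first grid point wins ties
tune_classifier <- function(id, x, y, grid, inner_folds, seed) {
  cand <- expand_grid_list(grid)
  if (length(cand) == 1L) return(cand[[1L]])
  fold <- stratified_folds(y, inner_folds, seed)
  acc <- vapply(cand, function(params) {
    correct <- 0L
    for (f in sort(unique(fold))) {
      tr <- fold != f
      fit <- fit_classifier(id, x[tr, , drop = FALSE], y[tr], params)
      pred <- predict_classifier(fit, x[!tr, , drop = FALSE])$class
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  cand[[which.max(acc)]]
}

#' Nested cross-validation of one strategy/classifier pair
#'
#' Outer stratified folds estimate performance; within each outer training
#' fold the classifier's hyperparameters are grid-searched by inner
#' stratified cross-validation, and the dimension reduction is fitted on the
#' outer training fold only (unless \code{config$transductive}) and applied
#' to the held-out fold. Metrics (accuracy, macro precision/recall/F1,
#' Hand-Till AUC) are averaged over the outer folds. Fully seeded: the same
#' configuration and seed reproduce the result bit for bit.
#'
#' Naive Bayes on unreduced data fails when any training feature has zero
#' variance; that combination returns a flagged all-\code{NA} report instead
#' of an error, mirroring how such cells are reported in practice.
#'
#' @param data An \code{"expr_data"} list (or list with \code{x} and
#'   \code{labels}).
#' @param config An \code{\link{experiment_config}}.
#' @param strategy One of the configured reduction strategies.
#' @param classifier One classifier id.
#' @param dataset_name Name used (with the strategy and classifier) to
#'   derive this task's fold seeds from the master seed.
#' @return A \code{"metrics_report"} whose entries are outer-fold averages,
#'   with attributes \code{folds} (per-fold reports), \code{d} (median
#'   retained dimension) and, when the task is skipped, \code{flagged}.
#' @export
nested_cv_evaluate <- function(data, config, strategy, classifier,
                               dataset_name = "data") {
  x <- as_data_matrix(data$x)
  y <- factor(data$labels)
  if (is.null(data$labels)) stop("dataset is unlabeled", call. = FALSE)
  task_seed <- string_seed(config$seed, dataset_name, strategy, classifier)
  # scope the RNG to this task so stochastic learners (random forest, SVM
  # probability model) are reproducible and order-independent
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(task_seed)

  if (classifier == "nb" && strategy == "AV" &&
      any(apply(x, 2, stats::var) == 0)) {
    rep <- empty_report(flag = paste(
      "naive Bayes skipped on unreduced data:",
      "at least one feature has zero variance"))
    return(rep)
  }

  reduction_full <- if (config$transductive)
    apply_reduction(strategy, x, x, config) else NULL
  fold <- stratified_folds(y, config$folds, task_seed)
  reports <- list()
  dims <- integer(0)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2L)
      stop("configuration error: outer training fold is single-class",
           call. = FALSE)
    if (config$transductive) {
      red <- list(train = reduction_full$train[tr, , drop = FALSE],
                  test = reduction_full$train[!tr, , drop = FALSE],
                  d = reduction_full$d)
    } else {
      red <- apply_reduction(strategy, x[tr, , drop = FALSE],
                             x[!tr, , drop = FALSE], config)
    }
    params <- tune_classifier(classifier, red$train, y[tr],
                              config$grids[[classifier]],
                              config$inner_folds,
                              string_seed(task_seed, "inner", f))
    fit <- fit_classifier(classifier, red$train, y[tr], params)
    pred <- predict_classifier(fit, red$test)
    reports[[length(reports) + 1L]] <-
      macro_metrics(y[!tr], pred$class, scores = pred$prob)
    dims <- c(dims, red$d)
  }
  avg <- average_reports(reports)
  attr(avg, "folds") <- reports
  attr(avg, "d") <- as.integer(stats::median(dims))
  avg
}

empty_report <- function(flag = NULL) {
  rep <- structure(list(accuracy = NA_real_, macro_precision = NA_real_,
                        macro_recall = NA_real_, macro_f1 = NA_real_,
                        auc = NA_real_, per_class = NULL, k = NA_integer_,
                        undefined_precision = character(0)),
                   class = "metrics_report")
  if (!is.null(flag)) attr(rep, "flagged") <- flag
  rep
}

average_reports <- function(reports) {
  fields <- c("accuracy", "macro_precision", "macro_recall", "macro_f1",
              "auc")
  out <- empty_report()
  for (f in fields)
    out[[f]] <- mean(vapply(reports, `[[`, numeric(1), f))
  out$k <- reports[[1L]]$k
  out
}

#' Run a full comparison experiment
#'
#' Evaluates every (dataset, strategy, classifier) combination with
#' \code{\link{nested_cv_evaluate}} and assembles the tidy results grid used
#' by \code{\link{opr}} and \code{\link{copr}}. Per-task seeds are derived
#' from the master seed and the task names, so the table content does not
#' depend on the order of datasets, strategies or classifiers.
#'
#' @param datasets Named list of labeled \code{"expr_data"} datasets.
#' @param config An \code{\link{experiment_config}}.
#' @return A \code{"results_table"} data frame (long form) with an
#'   additional \code{n_features} column; flagged (skipped) tasks carry
#'   \code{NA} values.
#' @export
run_experiment <- function(datasets, config = experiment_config()) {
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    stop("datasets must be a named list", call. = FALSE)
  rows <- list()
  metrics <- c(accuracy = "accuracy", macro_recall = "macro_recall",
               macro_precision = "macro_precision", macro_f1 = "macro_f1")
  for (ds in sort(names(datasets)))
    for (strategy in config$strategies)
      for (cl in config$classifiers) {
        rep <- nested_cv_evaluate(datasets[[ds]], config, strategy, cl,
                                  dataset_name = ds)
        for (mt in names(metrics))
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = ds, classifier = cl, strategy = strategy,
            n_features = attr(rep, "d") %||% NA_integer_,
            metric = mt, value = rep[[metrics[[mt]]]],
            stringsAsFactors = FALSE)
      }
  as_results_table(do.call(rbind, rows))
}

#' Format a results table as one block per dataset
#'
#' Mirrors the published per-dataset layout: one row per
#' (classifier, strategy) method, columns Method, Number of Features,
#' Accuracy, Macro-Recall, Macro-Precision, Macro-F1.
#'
#' @param results A \code{"results_table"}.
#' @return Named list of data frames, one per dataset.
#' @export
format_results_tables <- function(results) {
  out <- list()
  for (ds in unique(results$dataset)) {
    sub <- results[results$dataset == ds, ]
    wide <- stats::reshape(
      sub[, c("classifier", "strategy", "n_features", "metric", "value")],
      direction = "wide", idvar = c("classifier", "strategy",
                                    "n_features"),
      timevar = "metric")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide <- data.frame(
      method = paste(wide$classifier, wide$strategy, sep = "_"),
      n_features = wide$n_features,
      accuracy = wide$accuracy, macro_recall = wide$macro_recall,
      macro_precision = wide$macro_precision, macro_f1 = wide$macro_f1)
    out[[ds]] <- wide
  }
  out
}
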