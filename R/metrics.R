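#' Accuracy and macro-averaged classification metrics
#'
#' Treats each class in turn as the positive class against the rest, computes
#' per-class precision, recall and F1 from the confusion matrix, and averages
#' them without class-size weighting (macro averaging). Accuracy is the plain
#' fraction of correct predictions. A class never predicted has undefined
#' precision; it is scored 0 for that class and flagged, so the macro
#' averages stay computable.
#'
#' @param y_true True class labels.
#' @param y_pred Predicted class labels, same length.
#' @param scores Optional per-sample per-class score matrix (columns named by
#'   class); when supplied, the Hand-Till multiclass AUC is included.
#' @return An object of class \code{"metrics_report"}: a list with
#'   \code{accuracy}, \code{macro_precision}, \code{macro_recall},
#'   \code{macro_f1}, \code{auc} (\code{NA} without scores), a
#'   \code{per_class} data frame, the class count \code{k}, and
#'   \code{undefined_precision} naming classes scored 0 by convention.
#' @examples
#' macro_metrics(c(1, 1, 2, 2), c(1, 2, 1, 2))  # all macro metrics 0.5
#' @export
macro_metrics <- function(y_true, y_pred, scores = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length", call. = FALSE)
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  classes <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  yt <- factor(as.character(y_true), levels = classes)
  yp <- factor(as.character(y_pred), levels = classes)
  cm <- table(truth = yt, pred = yp)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  undef <- classes[(tp + fp) == 0]
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  auc <- if (is.null(scores)) NA_real_ else hand_till_auc(y_true, scores)
  structure(list(
    accuracy = mean(yt == yp),
    macro_precision = mean(prec),
    macro_recall = mean(rec),
    macro_f1 = mean(f1),
    auc = auc,
    per_class = data.frame(class = classes, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1),
                           row.names = NULL),
    k = length(classes),
    undefined_precision = undef), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | macroP %.4f | macroR %.4f | macroF1 %.4f | AUC %s\n",
    x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
    if (is.na(x$auc)) "-" else sprintf("%.4f", x$auc)))
  if (length(x$undefined_precision))
    cat("precision undefined (scored 0) for:",
        paste(x$undefined_precision, collapse = ", "), "\n")
  invisible(x)
}

# one-direction rank probability P(score of a random i-sample > score of a
# random j-sample), ties counting one half (midranks)
rank_prob <- function(scores_i, scores_j) {
  ni <- length(scores_i); nj <- length(scores_j)
  r <- rank(c(scores_i, scores_j), ties.method = "average")
  (sum(r[seq_len(ni)]) - ni * (ni + 1) / 2) / (ni * nj)
}

#' Hand-Till multiclass AUC
#'
#' Averages pairwise class-separability AUCs:
#' \eqn{M = \frac{2}{k(k-1)} \sum_{i<j} \hat A(i, j)} where
#' \eqn{\hat A(i, j)} averages the probability that a random class-i sample
#' outranks a random class-j sample under the class-i score column and the
#' converse probability under the class-j column; tied scores contribute one
#' half. Class pairs with no observed members of one class are skipped with
#' a warning and the divisor adjusted.
#'
#' @param y_true True class labels.
#' @param scores Numeric matrix, one row per sample and one column per
#'   class; column names (or order of \code{sort(unique(y_true))}) identify
#'   classes.
#' @return The multiclass AUC in \eqn{[0, 1]}.
#' @export
hand_till_auc <- function(y_true, scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y_true))
    stop("scores must have one row per sample", call. = FALSE)
  yt <- as.character(y_true)
  present <- sort(unique(yt))
  if (length(present) < 2L)
    stop("Hand-Till AUC is undefined with a single observed class",
         call. = FALSE)
  cls <- colnames(scores)
  if (is.null(cls)) {
    cls <- sort(unique(yt))
    if (length(cls) != ncol(scores))
      stop("unnamed score columns do not match the observed classes",
           call. = FALSE)
    colnames(scores) <- cls
  }
  missing_cls <- setdiff(present, cls)
  if (length(missing_cls))
    stop("no score column for class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  absent <- setdiff(cls, present)
  if (length(absent))
    warning("class(es) with zero samples skipped in AUC: ",
            paste(absent, collapse = ", "), call. = FALSE)
  pairs <- utils::combn(present, 2L)
  total <- 0
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    si <- yt == i; sj <- yt == j
    a_ij <- rank_prob(scores[si, i], scores[sj, i])
    a_ji <- rank_prob(scores[sj, j], scores[si, j])
    total <- total + (a_ij + a_ji) / 2
  }
  total / ncol(pairs)
}
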