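#' Confusion matrix
#'
#' Counts with rows = actual class and columns = predicted class.
#'
#' @param actual,predicted Label vectors of equal length.
#' @param classes Ordered class labels (default: sorted union).
#' @return Integer K x K matrix of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(actual, predicted,
                             classes = sort(unique(c(as.character(actual),
                                                     as.character(predicted))))) {
  if (length(actual) != length(predicted)) {
    stop("confusion_matrix: actual and predicted differ in length")
  }
  a <- factor(as.character(actual), levels = classes)
  p <- factor(as.character(predicted), levels = classes)
  if (anyNA(a) || anyNA(p)) stop("confusion_matrix: labels outside 'classes'")
  m <- unclass(table(actual = a, predicted = p))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Truncate to four decimals
#'
#' Reporting convention for accuracies: truncation (not rounding) to four
#' decimal places, e.g. 113/129 = 0.87596... reports as 0.8759.
#'
#' @param x Numeric.
#' @return \code{floor(x * 10^4) / 10^4} (with a tiny guard against
#'   floating-point representation error).
#' @export
truncate4 <- function(x) floor(x * 1e4 + 1e-9) / 1e4

#' Per-class and mean accuracy of a confusion matrix
#'
#' Per-class accuracy is the diagonal count over the row sum; the mean
#' accuracy is the unweighted arithmetic mean of the per-class accuracies
#' (not the pooled accuracy). Full precision is returned; \code{truncated}
#' carries the 4-decimal truncated reporting values.
#'
#' @param cm A [confusion_matrix()].
#' @return List with \code{per_class}, \code{mean}, and \code{truncated}
#'   (list of the same two, truncated to 4 decimals).
#' @export
class_accuracies <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    stop(sprintf("class_accuracies: no observations of class(es): %s",
                 paste(rownames(cm)[rs == 0], collapse = ", ")))
  }
  per_class <- diag(cm) / rs
  res <- list(per_class = per_class, mean = mean(per_class))
  res$truncated <- list(per_class = truncate4(per_class),
                        mean = truncate4(res$mean))
  res
}

#' Per-group accuracy report
#'
#' @param actual,predicted Label vectors.
#' @param group Grouping vector (e.g. infant sex) of the same length.
#' @return data.frame with correct, incorrect, total and accuracy
#'   (4-decimal truncated in \code{accuracy}; full precision in
#'   \code{accuracy_full}) per group.
#' @export
grouped_report <- function(actual, predicted, group) {
  stopifnot(length(actual) == length(predicted),
            length(actual) == length(group))
  g <- factor(group)
  correct <- tapply(as.character(actual) == as.character(predicted), g, sum)
  total <- as.integer(table(g))
  data.frame(group = levels(g), correct = as.integer(correct),
             incorrect = total - as.integer(correct), total = total,
             accuracy = truncate4(correct / total),
             accuracy_full = as.numeric(correct / total),
             row.names = NULL)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps a threshold over that class's vote score against
#' all others and integrates the ROC curve by the trapezoid rule.
#'
#' @param actual Label vector.
#' @param scores Matrix of per-class scores (rows sum to 1), columns named
#'   by class.
#' @param classes Ordered class labels (default: score column names).
#' @return List with per-class elements (each a list \code{curve}
#'   (data.frame fpr/tpr) and \code{auc}) plus \code{macro_auc}.
#' @export
roc_ovr <- function(actual, scores, classes = colnames(scores)) {
  scores <- as.matrix(scores)
  out <- list()
  aucs <- numeric(0)
  for (cl in classes) {
    pos <- as.character(actual) == cl
    s <- scores[, cl]
    ord <- order(s, decreasing = TRUE)
    pos_o <- pos[ord]
    s_o <- s[ord]
    tp <- cumsum(pos_o)
    fp <- cumsum(!pos_o)
    # collapse tied scores to single cut points
    last_of_tie <- c(s_o[-1L] != s_o[-length(s_o)], TRUE)
    tpr <- c(0, tp[last_of_tie] / max(sum(pos), 1L))
    fpr <- c(0, fp[last_of_tie] / max(sum(!pos), 1L))
    auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
    out[[cl]] <- list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
    aucs[cl] <- auc
  }
  out$macro_auc <- mean(aucs)
  out
}

#' Stratified k-fold cross-validation of the full ensemble
#'
#' Splits the rows into k stratified folds (each row validates exactly
#' once), trains a fresh grouped-support-vector network per fold, and
#' aggregates the out-of-fold predictions into one confusion matrix with
#' per-class/mean accuracies and one-vs-rest ROC.
#'
#' @param features Feature data.frame with a \code{label} column.
#' @param k Number of folds (default 10).
#' @param n_members,C,gamma,split,mode Passed to [train_gsvn()].
#' @param seed Integer seed (folds and per-fold training seeds derive from
#'   it).
#' @param group Optional grouping vector (e.g. sex) for a per-group report.
#' @return An \code{eval_report}: list with \code{confusion},
#'   \code{per_class_accuracy}, \code{mean_accuracy}, \code{fold_results},
#'   \code{roc}, \code{predictions}, and optionally \code{group_report}.
#' @export
kfold_cv <- function(features, k = 10L, n_members = 300L, C = 1, gamma = 0.1,
                     split = 0.8, mode = "boost", seed = 1L, group = NULL) {
  d <- split_label(features)
  set.seed(seed)
  fold <- stratified_folds(d$y, k)
  classes <- levels(d$y)
  n <- length(d$y)
  oof_pred <- character(n)
  oof_scores <- matrix(NA_real_, nrow = n, ncol = length(classes),
                       dimnames = list(NULL, classes))
  fold_results <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- features[fold != f, , drop = FALSE]
    attr(tr, "schema") <- attr(features, "schema")
    attr(tr, "families") <- attr(features, "families")
    model <- train_gsvn(tr, n_members = n_members, C = C, gamma = gamma,
                        split = split, seed = seed + f, mode = mode)
    pr <- predict(model, features[fold == f, , drop = FALSE])
    oof_pred[fold == f] <- as.character(pr$labels)
    oof_scores[fold == f, ] <- pr$scores
    cm_f <- confusion_matrix(d$y[fold == f], pr$labels, classes)
    fold_results[[f]] <- list(fold = f, confusion = cm_f,
                              accuracy = mean(as.character(pr$labels) ==
                                                as.character(d$y[fold == f])))
  }
  cm <- confusion_matrix(d$y, oof_pred, classes)
  acc <- class_accuracies(cm)
  report <- list(confusion = cm, per_class_accuracy = acc$per_class,
                 mean_accuracy = acc$mean, truncated = acc$truncated,
                 fold_results = fold_results,
                 roc = roc_ovr(d$y, oof_scores, classes),
                 predictions = data.frame(actual = as.character(d$y),
                                          predicted = oof_pred, fold = fold),
                 k = k, seed = seed)
  if (!is.null(group)) report$group_report <- grouped_report(d$y, oof_pred, group)
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV, mean accuracy %.4f\n", x$k,
              x$mean_accuracy))
  print(unclass(x$confusion))
  invisible(x)
}
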