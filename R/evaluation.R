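#' Classification accuracy (fraction correct)
#'
#' The fraction of cells whose predicted population equals the true one,
#' `(1/N) * sum(1(y_hat_i == y_i))`. This is the headline accuracy in both
#' the binary and multiclass setting.
#'
#' @param y_true,y_pred Label vectors of equal positive length.
#' @return A proportion in `[0, 1]`.
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("y_true and y_pred must have equal length >= 1")
  }
  mean(as.character(y_true) == as.character(y_pred))
}

#' Macro-averaged one-vs-rest accuracy
#'
#' The per-class mean of `(tp_j + tn_j) / (tp_j + tn_j + fp_j + fn_j)`,
#' averaging over classes. In the binary case this coincides with
#' [accuracy()]; for S > 2 it counts true negatives and systematically
#' exceeds the fraction correct, so it serves as a cross-check rather than
#' the headline metric.
#'
#' @inheritParams accuracy
#' @param classes Class set; defaults to the union of observed labels.
#' @return A proportion in `[0, 1]`.
#' @export
accuracy_macro <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("y_true and y_pred must have equal length >= 1")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(union(y_true, y_pred))
  n <- length(y_true)
  mean(vapply(classes, function(j) {
    tp <- sum(y_true == j & y_pred == j)
    tn <- sum(y_true != j & y_pred != j)
    (tp + tn) / n
  }, 0))
}

#' Binary AUC by the rank (Mann-Whitney) statistic
#'
#' Area under the ROC curve for a binary problem: the probability that a
#' randomly chosen positive receives a higher score than a randomly chosen
#' negative, ties counted half. Computed from rank sums, equivalent to the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`, and therefore
#' insensitive to class imbalance and invariant under strictly monotone
#' transforms of the scores.
#'
#' @param y_true Binary labels; `positive` names the positive class.
#' @param scores Finite numeric score for the positive class, one per label.
#' @param positive The positive-class label; defaults to the last of the two
#'   sorted observed labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_binary <- function(y_true, scores, positive = NULL) {
  if (length(y_true) != length(scores)) {
    stop("y_true and scores must have equal length")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  y_true <- as.character(y_true)
  classes <- sort(unique(y_true))
  if (length(classes) != 2L) {
    stop("AUC requires exactly two observed classes (got ",
         length(classes), "); it is undefined otherwise")
  }
  if (is.null(positive)) positive <- classes[2L]
  if (!positive %in% classes) stop("positive class '", positive,
                                   "' not among observed labels")
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Root mean squared error between target and predicted abundances
#'
#' `sqrt(mean((p_i - p_hat_i)^2))` over the n communities of an abundance
#' gradient; zero exactly when every prediction matches its target.
#'
#' @param p_target,p_pred Numeric vectors of equal length `n >= 1`.
#' @return Non-negative RMSE.
#' @export
rmse_gradient <- function(p_target, p_pred) {
  if (length(p_target) != length(p_pred) || length(p_target) < 1L) {
    stop("p_target and p_pred must have equal length >= 1")
  }
  sqrt(mean((p_target - p_pred)^2))
}

#' Confusion matrix with row-normalised fractions
#'
#' Cross-tabulates true against predicted labels. Entry `m[i, j]` of the
#' normalised matrix gives the fraction of population i predicted as
#' population j, so rows with support sum to 1; rows with zero support are
#' all-zero and flagged. Raw counts are retained alongside.
#'
#' @param y_true,y_pred Label vectors of equal length, drawn from `classes`.
#' @param classes Ordered class set; defaults to sorted observed labels.
#' @return List of class `confusion_matrix` with `counts`, `fractions`,
#'   `classes` and `zero_support` (logical per class).
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(union(y_true, y_pred))
  unknown <- setdiff(union(y_true, y_pred), classes)
  if (length(unknown)) {
    stop("label(s) outside the class set: ", paste(unknown, collapse = ", "))
  }
  counts <- table(factor(y_true, classes), factor(y_pred, classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  support <- rowSums(counts)
  fractions <- counts / ifelse(support > 0, support, 1)
  fractions[support == 0, ] <- 0
  structure(list(counts = counts, fractions = fractions, classes = classes,
                 zero_support = support == 0),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat("confusion_matrix (row-normalised fractions; rows = true):\n")
  print(round(x$fractions, digits))
  if (any(x$zero_support)) {
    cat("zero-support class(es): ",
        paste(x$classes[x$zero_support], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-community metrics on a held-out test set
#'
#' Convenience wrapper computing accuracy, the confusion matrix and (for
#' S = 2) the AUC of a fitted classifier on labelled test events.
#'
#' @param model A `cell_classifier`.
#' @param events Test `event_matrix` (or the `test` part is taken from a
#'   `split_community`).
#' @param labels True labels, one per test event.
#' @return List of class `metrics_report` with `accuracy`, `auc` (NA unless
#'   binary), `confusion` and `n_test`.
#' @export
evaluate_classifier <- function(model, events, labels = NULL) {
  if (inherits(events, "split_community")) {
    labels <- events$test$labels
    events <- events$test$events
  }
  stopifnot(inherits(model, "cell_classifier"))
  if (is.null(labels) || length(labels) != n_events(events)) {
    stop("labels must be supplied, one per test event")
  }
  y_true <- as.character(labels)
  y_pred <- as.character(predict(model, events, type = "class"))
  auc <- NA_real_
  if (length(model$classes) == 2L && length(unique(y_true)) == 2L) {
    scores <- predict(model, events, type = "prob")[, model$classes[2L]]
    auc <- auc_binary(y_true, scores, positive = model$classes[2L])
  }
  structure(list(accuracy = accuracy(y_true, y_pred), auc = auc,
                 confusion = confusion_matrix(y_true, y_pred, model$classes),
                 n_test = length(y_true)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report: accuracy = ", round(x$accuracy, 4), sep = "")
  if (!is.na(x$auc)) cat(", AUC = ", round(x$auc, 4), sep = "")
  cat(" (n_test = ", x$n_test, ")\n", sep = "")
  invisible(x)
}
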