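#' Fit a single-cell population classifier
#'
#' Trains a supervised classifier to predict the population of origin of
#' individual cells from their multiparametric cytometric fingerprint.
#' Two methods are supported, both operating on the raw stored intensities
#' without standardisation:
#'
#' * `"LDA"` — linear discriminant analysis: class-conditional Gaussians
#'   with a shared covariance, no hyperparameters, natural multiclass
#'   handling; posterior class probabilities follow from Bayes' theorem.
#' * `"RF"` — a random forest of `ntree` unpruned, decorrelated trees grown
#'   on bootstrap samples, Gini split criterion, with `mtry` features
#'   available per split (default `floor(sqrt(K))` for K channels, i.e. 3
#'   for the canonical 12-channel panel); class scores are the fraction of
#'   trees voting for each class.
#'
#' @param events Training `event_matrix`, or a `split_community` /
#'   `insilico_community` (whose training part / full labelled set is used).
#' @param labels Per-event population labels (ignored when `events` carries
#'   its own labels).
#' @param method `"RF"` (default) or `"LDA"`.
#' @param ntree Number of trees for `"RF"` (default 200).
#' @param mtry Features available per split for `"RF"`; default
#'   `floor(sqrt(K))`.
#' @param arcsinh_features If `TRUE`, arcsinh-transform all feature channels
#'   before fitting (and, consistently, before prediction). Off by default:
#'   classifiers consume the raw intensities.
#' @param seed Integer seed; makes random-forest training reproducible.
#' @return An object of class `cell_classifier` with fields `method`,
#'   `classes`, `channels`, `ntree`, `mtry`, `fit` (the underlying model) and
#'   `seed`.
#' @seealso [predict.cell_classifier()], [estimate_composition()]
#' @examples
#' pair <- preset_pairs()$high
#' panel <- simulate_panel(pair, replicates = 1, n_events = 800, seed = 1)
#' comm <- build_even_community(panel_samples(panel), n_per_pop = 500, seed = 2)
#' sp <- split_train_test(comm, seed = 3)
#' fit <- fit_cell_classifier(sp, method = "RF", seed = 4)
#' pred <- predict(fit, sp$test$events)
#' mean(pred == sp$test$labels)
#' @export
fit_cell_classifier <- function(events, labels = NULL,
                                method = c("RF", "LDA"), ntree = 200L,
                                mtry = NULL, arcsinh_features = FALSE,
                                seed = 1L) {
  method <- match.arg(method)
  if (inherits(events, "split_community")) {
    labels <- events$train$labels
    events <- events$train$events
  } else if (inherits(events, "insilico_community")) {
    labels <- events$labels
    events <- events$events
  }
  stopifnot(inherits(events, "event_matrix"))
  if (is.null(labels) || length(labels) != n_events(events)) {
    stop("labels must be supplied, one per training event")
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) {
    stop("training set must contain at least 2 distinct population labels")
  }
  x <- events$values
  if (any(!is.finite(x))) stop("training features must be finite")
  if (arcsinh_features) x <- asinh(x)
  K <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(K)))
  if (mtry < 1L || mtry > K) stop("mtry must lie in [1, ", K, "]")
  if (method == "RF" && ntree < 1L) stop("ntree must be >= 1")
  # data frame with syntactic names; channel mapping kept for prediction
  feat <- as.data.frame(x)
  names(feat) <- paste0("ch", seq_len(K))
  fit <- switch(method,
    LDA = MASS::lda(feat, grouping = labels),
    RF = with_seed(seed,
      randomForest::randomForest(feat, y = labels, ntree = as.integer(ntree),
                                 mtry = as.integer(mtry)))
  )
  structure(list(method = method, classes = levels(labels),
                 channels = channels(events), ntree = as.integer(ntree),
                 mtry = as.integer(mtry),
                 arcsinh_features = isTRUE(arcsinh_features),
                 fit = fit, seed = as.integer(seed)),
            class = "cell_classifier")
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat("cell_classifier (", x$method, ")\n", sep = "")
  cat("  classes:  ", paste(x$classes, collapse = ", "), "\n", sep = "")
  cat("  channels: ", length(x$channels), " (",
      paste(utils::head(x$channels, 4L), collapse = ", "),
      if (length(x$channels) > 4L) ", ..." else "", ")\n", sep = "")
  if (x$method == "RF") {
    cat("  forest:   ", x$ntree, " trees, mtry = ", x$mtry, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cell_classifier <- function(object, ...) {
  print(object)
  if (object$method == "RF") {
    err <- object$fit$err.rate[object$ntree, "OOB"]
    cat("  OOB error estimate: ", signif(err, 4), "\n", sep = "")
  }
  invisible(object)
}

classifier_features <- function(model, events) {
  stopifnot(inherits(events, "event_matrix"))
  miss <- setdiff(model$channels, channels(events))
  if (length(miss)) {
    stop("events lack training channel(s): ", paste(miss, collapse = ", "))
  }
  x <- events$values[, model$channels, drop = FALSE]
  if (model$arcsinh_features) x <- asinh(x)
  feat <- as.data.frame(x)
  names(feat) <- paste0("ch", seq_along(model$channels))
  feat
}

#' Predict population labels or class scores for cells
#'
#' @param object A `cell_classifier`.
#' @param events An `event_matrix` carrying (at least) the training channels.
#' @param type `"class"` for hard labels, `"prob"` for per-class scores.
#'   Scores are posterior probabilities (LDA) or tree-vote fractions (RF);
#'   each row sums to 1 and the row-wise argmax equals the hard label, ties
#'   broken towards the first class in `object$classes` order.
#' @param ... Unused.
#' @return Factor of labels (levels `object$classes`), or a numeric matrix
#'   of scores with one column per class.
#' @export
predict.cell_classifier <- function(object, events, type = c("class", "prob"),
                                    ...) {
  type <- match.arg(type)
  feat <- classifier_features(object, events)
  if (nrow(feat) == 0L) {
    if (type == "class") {
      return(factor(character(0), levels = object$classes))
    }
    return(matrix(numeric(0), 0L, length(object$classes),
                  dimnames = list(NULL, object$classes)))
  }
  scores <- switch(object$method,
    LDA = stats::predict(object$fit, feat)$posterior,
    RF = stats::predict(object$fit, feat, type = "prob")
  )
  scores <- scores[, object$classes, drop = FALSE]
  scores <- scores / rowSums(scores)
  if (type == "prob") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Estimate community composition by plug-in cell counting
#'
#' Classifies every cell of a community and estimates the relative abundance
#' of each population as the fraction of cells assigned to it (the plug-in
#' count estimator).
#'
#' @param model A `cell_classifier`.
#' @param events A non-empty `event_matrix` (or `insilico_community`).
#' @return An object of class `composition_estimate` with `taxa`, `counts`
#'   and `p_hat` (proportions summing to 1).
#' @export
estimate_composition <- function(model, events) {
  if (inherits(events, "insilico_community")) events <- events$events
  stopifnot(inherits(model, "cell_classifier"))
  if (n_events(events) == 0L) {
    stop("cannot estimate a composition from zero events")
  }
  pred <- predict(model, events, type = "class")
  counts <- table(pred)[model$classes]
  structure(list(taxa = model$classes,
                 counts = stats::setNames(as.integer(counts), model$classes),
                 p_hat = stats::setNames(as.numeric(counts) / length(pred),
                                         model$classes)),
            class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, ...) {
  df <- data.frame(taxon = x$taxa, count = x$counts,
                   p_hat = round(x$p_hat, 4))
  cat("composition_estimate (", sum(x$counts), " cells)\n", sep = "")
  print(df, row.names = FALSE)
  invisible(x)
}
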