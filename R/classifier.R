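# Random-forest behaviour classifier: OOB-based mtry tuning, seeded
# training, vote-based prediction with deterministic tie-breaking, and the
# confusion-matrix / precision / recall / MCC evaluation.

.feature_cols <- function(x) {
  cols <- intersect(feature_names(), names(x))
  if (length(cols) == 0L) {
    stop("no feature columns found (see feature_names())", call. = FALSE)
  }
  cols
}

#' Tune mtry by out-of-bag error
#'
#' Fits one forest per candidate number of predictors per split and returns
#' the candidate with the lowest out-of-bag error rate; ties go to the
#' smallest candidate. The candidate set defaults to a geometric
#' neighbourhood of `floor(sqrt(36)) = 6`, emulating a doubling/halving
#' search around the usual classification default.
#'
#' @param train data.frame with a `label` column and the 36 feature columns.
#' @param candidates Integer candidates for mtry (all must be between 1 and
#'   the number of features).
#' @param n_trees Trees per candidate forest.
#' @param seed Integer seed, reused for every candidate fit.
#' @return The selected mtry (integer) with attribute `"oob_errors"`, the
#'   named per-candidate OOB error table, also reported via `message()`.
#' @export
tune_mtry <- function(train, candidates = c(3, 6, 9, 12, 18),
                      n_trees = 1000, seed = 1) {
  cols <- .feature_cols(train)
  if (any(candidates < 1 | candidates > length(cols))) {
    stop("mtry candidates must lie in [1, ", length(cols), "]",
         call. = FALSE)
  }
  candidates <- sort(unique(as.integer(candidates)))
  errs <- vapply(candidates, function(m) {
    train_forest(train, n_trees = n_trees, mtry = m, seed = seed)$oob_error
  }, numeric(1L))
  names(errs) <- candidates
  message("OOB error by mtry: ",
          paste(names(errs), sprintf("%.4f", errs), sep = "=",
                collapse = ", "))
  structure(candidates[which.min(errs)], oob_errors = errs)
}

#' Train the random-forest behaviour model
#'
#' Fits a seeded random forest (1000 trees by default) on the labelled
#' 36-feature windows and reports the out-of-bag error rate and confusion
#' matrix: each training window is scored only by the trees whose bootstrap
#' sample did not contain it, giving an internal estimate of generalisation
#' error without a held-out set.
#'
#' @param train data.frame with `label` plus feature columns; every feature
#'   must be finite and every ethogram class present in the labels must have
#'   at least one observation (a factor label with an empty level is
#'   rejected).
#' @param n_trees Number of trees.
#' @param mtry Predictors per split; default `floor(sqrt(p))`.
#' @param seed Integer seed; identical seeds reproduce the fit exactly.
#' @return Object of class `bear_forest`: list with `model` (the underlying
#'   randomForest fit), `feature_names`, `class_order`, `config`,
#'   `oob_error` and `oob_confusion` (rows = observed, columns = predicted).
#' @export
train_forest <- function(train, n_trees = 1000, mtry = NULL, seed = 1) {
  cols <- .feature_cols(train)
  stopifnot("label" %in% names(train), n_trees >= 1)
  x <- train[, cols, drop = FALSE]
  if (!all(vapply(x, function(v) all(is.finite(v)), logical(1L)))) {
    stop("all features must be finite", call. = FALSE)
  }
  lab <- train$label
  .assert_behaviors(lab)
  lev <- if (is.factor(lab)) intersect(bear_behaviors(), levels(lab))
         else intersect(bear_behaviors(), unique(as.character(lab)))
  y <- factor(as.character(lab), levels = lev)
  cnt <- table(y)
  if (any(cnt == 0L)) {
    stop("class with 0 observations: ",
         paste(names(cnt)[cnt == 0L], collapse = ", "), call. = FALSE)
  }
  if (length(lev) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(mtry)) mtry <- floor(sqrt(length(cols)))
  stopifnot(mtry >= 1, mtry <= length(cols))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    mtry = mtry)
  oob_err <- unname(fit$err.rate[n_trees, "OOB"])
  cm <- fit$confusion[, lev, drop = FALSE]
  storage.mode(cm) <- "integer"
  out <- list(model = fit,
              feature_names = cols,
              class_order = lev,
              config = list(n_trees = n_trees, mtry = mtry, seed = seed,
                            nodesize = 1, maxnodes = NULL),
              oob_error = oob_err,
              oob_confusion = cm)
  class(out) <- "bear_forest"
  out
}

#' @export
print.bear_forest <- function(x, ...) {
  cat(sprintf("Random-forest behaviour model: %d trees, mtry %d, seed %d\n",
              x$config$n_trees, x$config$mtry, x$config$seed))
  cat(sprintf("OOB error rate: %.3f\n", x$oob_error))
  cat("OOB confusion (rows observed, columns predicted):\n")
  print(x$oob_confusion)
  invisible(x)
}

#' Predict behaviours for unlabelled windows
#'
#' Majority vote over the forest's trees; exact vote ties are broken
#' deterministically in favour of the class earliest in the model's fixed
#' class order.
#'
#' @param model A [train_forest()] fit.
#' @param features data.frame containing the model's feature columns (extra
#'   columns are ignored; a missing feature column is an error naming it).
#' @return Factor of predicted labels with the model's class levels.
#' @export
predict_behaviors <- function(model, features) {
  stopifnot(inherits(model, "bear_forest"))
  miss <- setdiff(model$feature_names, names(features))
  if (length(miss) > 0L) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- features[, model$feature_names, drop = FALSE]
  if (nrow(x) == 0L) {
    return(factor(character(), levels = model$class_order))
  }
  votes <- predict(model$model, newdata = x, type = "vote",
                   norm.votes = FALSE)
  votes <- votes[, model$class_order, drop = FALSE]
  idx <- apply(votes, 1L, which.max)   # first max = earliest class on ties
  factor(model$class_order[idx], levels = model$class_order)
}

#' Confusion matrix of observed vs predicted behaviours
#'
#' @param obs,pred Equal-length label vectors; every label must be in
#'   `classes`.
#' @param classes Class order of the matrix axes.
#' @return Integer matrix, `counts[i, j]` = number of windows observed as
#'   class i and predicted as class j.
#' @export
confusion <- function(obs, pred, classes = bear_behaviors()) {
  if (length(obs) != length(pred)) {
    stop("obs and pred must have equal length", call. = FALSE)
  }
  .assert_behaviors(obs, classes, "observed label")
  .assert_behaviors(pred, classes, "predicted label")
  m <- table(factor(as.character(obs), levels = classes),
             factor(as.character(pred), levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(observed = classes, predicted = classes))
  out
}

#' Per-class precision, recall and Matthews correlation coefficient
#'
#' Collapses the multiclass confusion matrix one-vs-rest for each class and
#' computes `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, plus the
#' overall error (off-diagonal fraction) and accuracy. MCC is preferred over
#' accuracy for these data because the behaviour classes are strongly
#' imbalanced (running is rare). Any metric with a zero denominator is
#' reported as `NA`, never as 0.
#'
#' @param cm Square confusion matrix, rows observed, columns predicted, with
#'   non-negative counts and a positive total.
#' @return List with `per_class` (data.frame: class, TP, FP, TN, FN,
#'   precision, recall, mcc), `overall_error`, `overall_accuracy`, `total`.
#' @export
#' @examples
#' cm <- confusion(c("feeding", "resting"), c("resting", "resting"))
#' classification_metrics(cm)$overall_error
classification_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  cm <- matrix(as.numeric(cm), nrow = nrow(cm), dimnames = dimnames(cm))
  if (any(cm < 0)) stop("confusion counts must be non-negative",
                        call. = FALSE)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no observations",
                       call. = FALSE)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  per <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else NA_real_
    data.frame(class = classes[i], TP = tp, FP = fp, TN = tn, FN = fn,
               precision = prec, recall = rec, mcc = mcc)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  correct <- sum(diag(cm))
  list(per_class = per,
       overall_error = (total - correct) / total,
       overall_accuracy = correct / total,
       total = total)
}
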