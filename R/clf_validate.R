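#' Balanced accuracy of a prediction
#'
#' Mean per-class recall. Errors if any true class is absent.
#'
#' @param truth,pred factors (or vectors coercible to factors on the same
#'   levels).
#' @return a number in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  tab <- table(truth, pred)
  if (any(rowSums(tab) == 0)) stop("a true class has no samples")
  mean(diag(tab) / rowSums(tab))
}

# Uniform fit/predict contract around the standard classifier suite.
# These are validation instruments, not the selection method itself, so
# each is the stock implementation with fixed, documented defaults:
# decision_tree: rpart, unpruned (cp = 0) but depth-capped at 10
# knn:           class::knn, k = 5, features standardized on the training part
# random_forest: randomForest, 500 trees
# naive_bayes:   e1071::naiveBayes (Gaussian)
# svm:           e1071::svm, RBF kernel, cost = 1
#' Supported classifier names
#' @export
classifier_names <- function() {
  c("decision_tree", "knn", "random_forest", "naive_bayes", "svm")
}

fit_classifier <- function(name, x, y, params = list()) {
  y <- as.factor(y)
  df <- data.frame(x, check.names = FALSE)
  model <- switch(
    name,
    decision_tree = rpart::rpart(
      y ~ ., data = cbind(df, y = y), method = "class",
      control = rpart::rpart.control(
        cp = params$cp %||% 0, maxdepth = params$maxdepth %||% 10,
        xval = 0)),
    knn = {
      mu <- colMeans(x)
      sdv <- apply(x, 2, stats::sd)
      sdv[sdv == 0] <- 1
      list(train = scale(x, mu, sdv), y = y, mu = mu, sd = sdv,
           k = params$k %||% 5)
    },
    random_forest = randomForest::randomForest(
      x = x, y = y, ntree = params$ntree %||% 500),
    naive_bayes = e1071::naiveBayes(x = df, y = y),
    svm = e1071::svm(x = x, y = y, kernel = "radial",
                     cost = params$cost %||% 1),
    stop("unknown classifier: ", name))
  list(name = name, model = model, levels = levels(y),
       features = colnames(x))
}

predict_classifier <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  pred <- switch(
    fit$name,
    decision_tree = predict(fit$model, df, type = "class"),
    knn = class::knn(fit$model$train,
                     scale(x, fit$model$mu, fit$model$sd),
                     fit$model$y, k = fit$model$k),
    random_forest = predict(fit$model, x),
    naive_bayes = predict(fit$model, df),
    svm = predict(fit$model, x))
  factor(as.character(pred), levels = fit$levels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that every fold's class
#' proportions are within one sample of the global proportions.
#'
#' @param y class vector.
#' @param k number of folds.
#' @param seed optional integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of a feature subset
#'
#' Evaluates how well `feature_subset` predicts the class: per-fold
#' balanced accuracy on the held-out fold, classifier fitted on the rest.
#' Feature selection is assumed to have happened *outside* this function;
#' when the subset was selected on the same samples, the CV estimate is
#' optimistic (the honest figure comes from
#' [train_test_evaluate()] on unseen samples).
#'
#' @param ds an [omics_dataset()] with classes assigned, or matrix plus `y`.
#' @param feature_subset character vector of feature ids (non-empty).
#' @param classifier one of [classifier_names()].
#' @param k folds (default 10).
#' @param seed integer seed for the folding.
#' @param params classifier hyperparameter overrides.
#' @param y class vector when `ds` is a matrix.
#' @return a `cv_report` data.frame row set: one row per fold plus
#'   attributes `mean` and `sd`.
#' @export
cross_validate <- function(ds, feature_subset, classifier = "random_forest",
                           k = 10L, seed = NULL, params = list(), y = NULL) {
  if (length(feature_subset) == 0) stop("`feature_subset` is empty")
  classifier <- match.arg(classifier, classifier_names())
  if (k < 2) stop("`k` must be >= 2")
  xy <- resolve_xy(ds, y)
  x <- xy$x[, feature_subset, drop = FALSE]
  yf <- factor(xy$levels[xy$y + 1L], levels = xy$levels)
  fold <- stratified_folds(yf, k, seed)
  if (any(tapply(yf, fold, function(g) length(unique(g))) < 2))
    stop("every fold must contain both classes; reduce k")
  ba <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_classifier(classifier, x[tr, , drop = FALSE], yf[tr], params)
    balanced_accuracy(yf[!tr], predict_classifier(fit, x[!tr, , drop = FALSE]))
  }, 0)
  out <- data.frame(classifier = classifier, fold = seq_len(k),
                    balanced_accuracy = ba, stringsAsFactors = FALSE)
  attr(out, "mean") <- mean(ba)
  attr(out, "sd") <- stats::sd(ba)
  class(out) <- c("cv_report", "data.frame")
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV, %s: balanced accuracy %.3f +/- %.3f\n",
              max(x$fold), x$classifier[1], attr(x, "mean"), attr(x, "sd")))
  invisible(x)
}

#' Train/test evaluation of a feature subset
#'
#' Single fit on the training cohort, single evaluation on the disjoint
#' test cohort — the validation design for a pre-selected feature set on
#' unseen patients.
#'
#' @param train_ds,test_ds [omics_dataset()] objects with classes assigned
#'   and disjoint sample ids; both must contain `feature_subset`.
#' @param feature_subset character vector of feature ids.
#' @param classifier one of [classifier_names()].
#' @param params hyperparameter overrides.
#' @param allow_overlap sanity-mode override permitting train = test.
#' @return balanced accuracy on the test cohort.
#' @export
train_test_evaluate <- function(train_ds, test_ds, feature_subset,
                                classifier = "random_forest",
                                params = list(), allow_overlap = FALSE) {
  classifier <- match.arg(classifier, classifier_names())
  if (length(feature_subset) == 0) stop("`feature_subset` is empty")
  xytr <- resolve_xy(train_ds, NULL)
  xyte <- resolve_xy(test_ds, NULL)
  overlap <- intersect(rownames(xytr$x), rownames(xyte$x))
  if (length(overlap) && !allow_overlap)
    stop("train and test share ", length(overlap), " sample id(s)")
  miss <- setdiff(feature_subset,
                  intersect(colnames(xytr$x), colnames(xyte$x)))
  if (length(miss))
    stop("feature(s) absent from train or test: ",
         paste(utils::head(miss, 5), collapse = ", "))
  ytr <- factor(xytr$levels[xytr$y + 1L], levels = xytr$levels)
  yte <- factor(xyte$levels[xyte$y + 1L], levels = xytr$levels)
  fit <- fit_classifier(classifier, xytr$x[, feature_subset, drop = FALSE],
                        ytr, params)
  balanced_accuracy(yte,
                    predict_classifier(fit, xyte$x[, feature_subset, drop = FALSE]))
}

#' Run the full classifier suite
#'
#' Convenience wrapper producing one report per classifier, either by
#' cross-validation (`mode = "cv"`) or train/test evaluation.
#'
#' @param ds training dataset (or matrix with `y`).
#' @param feature_subset feature ids to use.
#' @param mode `"cv"` or `"traintest"`.
#' @param test_ds test dataset (required for `"traintest"`).
#' @param classifiers subset of [classifier_names()].
#' @param k,seed,params forwarded to [cross_validate()].
#' @param y class vector when `ds` is a matrix.
#' @return data.frame with one row per classifier: mean and sd of the
#'   balanced accuracy (sd NA in train/test mode).
#' @export
validate_features <- function(ds, feature_subset, mode = c("cv", "traintest"),
                              test_ds = NULL, classifiers = classifier_names(),
                              k = 10L, seed = NULL, params = list(), y = NULL) {
  mode <- match.arg(mode)
  rows <- lapply(classifiers, function(cl) {
    if (mode == "cv") {
      rep <- cross_validate(ds, feature_subset, cl, k = k, seed = seed,
                            params = params, y = y)
      data.frame(classifier = cl, mode = "cv",
                 balanced_accuracy = attr(rep, "mean"),
                 sd = attr(rep, "sd"), stringsAsFactors = FALSE)
    } else {
      if (is.null(test_ds)) stop("`test_ds` is required for train/test mode")
      ba <- train_test_evaluate(ds, test_ds, feature_subset, cl, params)
      data.frame(classifier = cl, mode = "traintest",
                 balanced_accuracy = ba, sd = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
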