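# Subject-level aggregation of the 12 per-slice age predictions.
#
# Tree ensembles (extremely randomized trees for regression, random forests
# for classification) are the default aggregators; SVM, linear regression,
# k-nearest-neighbours and gradient boosting are available as alternatives.
# Subjects under 18 years are the positive ("minor") class throughout.

MINOR_AGE_LIMIT <- 18

#' Specification of a subject-level aggregator
#'
#' @param task `"regression"` (final age estimate) or `"classification"`
#'   (minor vs adult).
#' @param algorithm one of `"extratrees"`, `"random_forest"`, `"svm"`,
#'   `"linear"`, `"knn"` (classification only), `"gradient_boosting"`.
#'   Defaults: extremely randomized trees for regression, random forest for
#'   classification.
#' @param num_trees trees for the ensemble algorithms.
#' @param seed RNG seed for the fit.
#' @param ... further hyperparameters passed to the backend.
#' @return an `aggregator_spec`.
#' @export
aggregator_spec <- function(task = c("regression", "classification"),
                            algorithm = NULL, num_trees = 500L, seed = 1L,
                            ...) {
  task <- match.arg(task)
  if (is.null(algorithm)) {
    algorithm <- if (task == "regression") "extratrees" else "random_forest"
  }
  valid <- c("extratrees", "random_forest", "svm", "linear", "knn",
             "gradient_boosting")
  if (!algorithm %in% valid) stop("unknown algorithm: ", algorithm)
  if (algorithm == "knn" && task == "regression") {
    stop("knn aggregation is available for classification only")
  }
  if (algorithm == "linear" && task == "classification") {
    stop("linear regression aggregation is available for regression only")
  }
  structure(list(task = task, algorithm = algorithm,
                 num_trees = as.integer(num_trees), seed = as.integer(seed),
                 extra = list(...)),
            class = "aggregator_spec")
}

as_feature_matrix <- function(rows) {
  x <- as.matrix(as.data.frame(rows))
  if (anyNA(x)) stop("feature rows contain missing values; subject-related data must be fully present or fully absent")
  x
}

#' Fit the subject-level age regressor
#'
#' Maps each subject's 12 slice predictions (optionally augmented with
#' subject-related data columns) to a final age estimate.
#'
#' @param rows feature matrix or data frame; 12 slice-prediction columns,
#'   optionally followed by subject-related data.
#' @param ages chronological ages (years), aligned with `rows`.
#' @param spec an [aggregator_spec()] with `task = "regression"`.
#' @return an `age_aggregator` usable with [predict_age()].
#' @export
fit_age_regressor <- function(rows, ages,
                              spec = aggregator_spec("regression")) {
  x <- as_feature_matrix(rows)
  if (nrow(x) != length(ages)) stop("feature/label length mismatch")
  if (nrow(x) < 2) stop("need at least two training rows")
  stopifnot(spec$task == "regression")
  df <- data.frame(x)
  df$.age <- ages
  fit <- switch(spec$algorithm,
    extratrees = ranger::ranger(.age ~ ., data = df,
                                num.trees = spec$num_trees,
                                splitrule = "extratrees",
                                num.random.splits = 1,
                                seed = spec$seed),
    random_forest = ranger::ranger(.age ~ ., data = df,
                                   num.trees = spec$num_trees,
                                   seed = spec$seed),
    svm = { requireNamespace("e1071")
            e1071::svm(.age ~ ., data = df) },
    linear = stats::lm(.age ~ ., data = df),
    gradient_boosting = { requireNamespace("xgboost")
      xgboost::xgboost(data = x, label = ages, nrounds = 200,
                       params = list(max_depth = 3, eta = 0.1,
                                     seed = spec$seed),
                       verbose = 0) })
  structure(list(spec = spec, fit = fit, colnames = colnames(df)[-ncol(df)]),
            class = "age_aggregator")
}

#' Predict final ages with a fitted aggregator
#' @param model an `age_aggregator` or [best_guess_regressor()].
#' @param rows feature rows as in [fit_age_regressor()].
#' @return numeric vector of age estimates (years).
#' @export
predict_age <- function(model, rows) UseMethod("predict_age")

#' @export
predict_age.age_aggregator <- function(model, rows) {
  x <- as_feature_matrix(rows)
  df <- data.frame(x)
  colnames(df) <- model$colnames
  switch(model$spec$algorithm,
    extratrees = ,
    random_forest = stats::predict(model$fit, data = df)$predictions,
    gradient_boosting = as.numeric(stats::predict(model$fit, x)),
    as.numeric(stats::predict(model$fit, newdata = df)))
}

#' Fit the minor/adult classifier
#'
#' @param rows feature rows as in [fit_age_regressor()].
#' @param minor logical (or 0/1) vector; `TRUE` marks minors (age under
#'   18), the positive class.
#' @param spec an [aggregator_spec()] with `task = "classification"`.
#' @return a `minor_classifier` emitting minor-probability scores.
#' @export
fit_minor_classifier <- function(rows, minor,
                                 spec = aggregator_spec("classification")) {
  x <- as_feature_matrix(rows)
  minor <- as.logical(minor)
  if (nrow(x) != length(minor)) stop("feature/label length mismatch")
  if (length(unique(minor)) < 2) stop("single-class training set")
  stopifnot(spec$task == "classification")
  df <- data.frame(x)
  df$.minor <- factor(ifelse(minor, "minor", "adult"),
                      levels = c("adult", "minor"))
  fit <- switch(spec$algorithm,
    random_forest = ranger::ranger(.minor ~ ., data = df,
                                   num.trees = spec$num_trees,
                                   probability = TRUE, seed = spec$seed),
    extratrees = ranger::ranger(.minor ~ ., data = df,
                                num.trees = spec$num_trees,
                                splitrule = "extratrees",
                                num.random.splits = 1,
                                probability = TRUE, seed = spec$seed),
    svm = { requireNamespace("e1071")
            e1071::svm(.minor ~ ., data = df, probability = TRUE) },
    knn = { requireNamespace("class")
            list(train = x, labels = minor, k = spec$extra$k %||% 5) },
    gradient_boosting = { requireNamespace("xgboost")
      xgboost::xgboost(data = x, label = as.numeric(minor), nrounds = 200,
                       params = list(max_depth = 3, eta = 0.1,
                                     objective = "binary:logistic",
                                     seed = spec$seed),
                       verbose = 0) })
  structure(list(spec = spec, fit = fit, colnames = colnames(df)[-ncol(df)]),
            class = "minor_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minor-probability scores and hard labels
#'
#' @param model a `minor_classifier` (or [naive_classifier()]).
#' @param rows feature rows.
#' @param threshold minor-probability cut for the hard label (default 0.5;
#'   raise it to trade sensitivity for specificity).
#' @return list with `score` (minor probability in [0, 1]) and `minor`
#'   (logical hard labels, `score >= threshold`).
#' @export
predict_minor <- function(model, rows, threshold = 0.5) {
  UseMethod("predict_minor")
}

#' @export
predict_minor.minor_classifier <- function(model, rows, threshold = 0.5) {
  x <- as_feature_matrix(rows)
  df <- data.frame(x)
  colnames(df) <- model$colnames
  score <- switch(model$spec$algorithm,
    random_forest = ,
    extratrees = stats::predict(model$fit, data = df)$predictions[, "minor"],
    svm = attr(stats::predict(model$fit, newdata = df, probability = TRUE),
               "probabilities")[, "minor"],
    knn = {
      pr <- class::knn(model$fit$train, x,
                       factor(model$fit$labels), k = model$fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "TRUE", p, 1 - p)
    },
    gradient_boosting = as.numeric(stats::predict(model$fit, x)))
  list(score = as.numeric(score), minor = score >= threshold)
}

#' Best-available-guess regressor
#'
#' The statistical-reference baseline for regression: a constant predictor
#' equal to the mean age of the training set.
#'
#' @param train_ages training ages (years), non-empty.
#' @return a `best_guess_regressor`; use [predict_age()] on it.
#' @export
best_guess_regressor <- function(train_ages) {
  if (length(train_ages) == 0) stop("empty training ages")
  structure(list(mean_age = mean(train_ages)), class = "best_guess_regressor")
}

#' @export
predict_age.best_guess_regressor <- function(model, rows) {
  n <- if (is.matrix(rows) || is.data.frame(rows)) nrow(rows)
       else length(rows)
  rep(model$mean_age, n)
}

#' Naive all-minors classifier
#'
#' The statistical-reference baseline for classification: every subject is
#' labelled a minor with a constant score, giving sensitivity 1, specificity
#' 0 and AUC 0.5 on any mixed test set.
#'
#' @return a `naive_classifier`; use [predict_minor()] on it.
#' @export
naive_classifier <- function() {
  structure(list(), class = "naive_classifier")
}

#' @export
predict_minor.naive_classifier <- function(model, rows, threshold = 0.5) {
  n <- if (is.matrix(rows) || is.data.frame(rows)) nrow(rows)
       else length(rows)
  list(score = rep(1, n), minor = rep(TRUE, n))
}
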