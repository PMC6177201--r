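#' Cross-validation scheme
#'
#' Two schemes are provided. `"stratified_kfold_trialwise"` deals the trials
#' of each class into `n_folds` folds at random (class counts balanced to
#' within one trial per fold); members of one subclass may — and generally do —
#' end up in both training and test folds, which is precisely what lets
#' subclass structure leak into cross-validated accuracy.
#' `"leave_one_subclass_out"` instead uses subclasses as folds: each fold
#' holds out one whole subclass per class, so no subclass is ever present in
#' both training and test data.
#'
#' @param kind One of `"stratified_kfold_trialwise"`,
#'   `"leave_one_subclass_out"` (abbreviations `"2fold"`/`"kfold"` and
#'   `"loso"` are accepted).
#' @param n_folds Number of folds for the trial-wise scheme (default 2,
#'   split-half). Ignored for leave-one-subclass-out, where the number of
#'   folds equals the number of subclasses per class.
#' @param seed Optional seed for the random fold assignment.
#' @return An object of class `"cv_scheme"`.
#' @export
cv_scheme <- function(kind = c("stratified_kfold_trialwise",
                               "leave_one_subclass_out",
                               "2fold", "kfold", "loso"),
                      n_folds = 2, seed = NULL) {
  kind <- match.arg(kind)
  kind <- switch(kind,
                 "2fold" = , "kfold" = "stratified_kfold_trialwise",
                 "loso" = "leave_one_subclass_out",
                 kind)
  n_folds <- as.integer(n_folds)
  if (is.na(n_folds) || n_folds < 2L) stop("'n_folds' must be >= 2")
  structure(list(kind = kind, n_folds = n_folds,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cv_scheme")
}

# Fold assignment as a list of test-trial index vectors covering all trials.
make_folds <- function(data, cv) {
  n <- nrow(data$features)
  if (cv$kind == "stratified_kfold_trialwise") {
    if (!is.null(cv$seed)) set.seed(cv$seed)
    fold <- integer(n)
    for (cl in unique(data$class)) {
      idx <- which(data$class == cl)
      fold[idx] <- sample(rep_len(seq_len(cv$n_folds), length(idx)))
    }
    lapply(seq_len(cv$n_folds), function(f) which(fold == f))
  } else {
    subs1 <- sort(unique(data$subclass[data$class == 1L]))
    subs2 <- sort(unique(data$subclass[data$class == 2L]))
    if (length(subs1) != length(subs2))
      stop("leave-one-subclass-out needs equal subclass counts per class")
    K <- length(subs1)
    if (K < 2L) stop("leave-one-subclass-out needs >= 2 subclasses per class")
    if (cv$n_folds > K)
      stop("fewer subclasses per class than requested folds")
    lapply(seq_len(K), function(j)
      which(data$subclass == subs1[j] | data$subclass == subs2[j]))
  }
}

# Internal lean fit of the mean-difference rule on a feature matrix.
.lda_fit <- function(x, cl) {
  if (length(unique(cl)) < 2L) stop("training data must contain both classes")
  m1 <- colMeans(x[cl == 1L, , drop = FALSE])
  m2 <- colMeans(x[cl == 2L, , drop = FALSE])
  w <- m1 - m2
  list(w = w, b = sum(w * (m1 + m2)) / 2)
}

# Scores >= 0 -> class 1 (ties go to class 1 by convention).
.lda_predict <- function(fit, x) {
  ifelse(drop(x %*% fit$w) - fit$b >= 0, 1L, 2L)
}

#' Mean-difference linear discriminant ("projection onto the class-mean axis")
#'
#' Fits the linear rule analysed by the chance-level theory: a test point is
#' projected onto the axis defined by the difference of the empirical class
#' means and assigned to whichever side of the midpoint threshold
#' \eqn{\theta = (\bar\mu + \bar\nu)/2} it falls on. Points landing exactly on
#' the threshold are assigned to class 1 (a probability-zero event for
#' continuous data; the convention only matters for constructed inputs).
#'
#' @param train A [nested_data()] object containing both classes.
#' @return An object of class `"linear_rule"` with a [predict()] method that
#'   maps a feature matrix to class labels in `{1, 2}`.
#' @export
#' @examples
#' dat <- toy_subclass_data(seed = 2)
#' rule <- fit_mean_diff_lda(dat)
#' table(predict(rule, dat$features), dat$class)
fit_mean_diff_lda <- function(train) {
  if (!inherits(train, "nested_data")) stop("'train' must be a nested_data object")
  fit <- .lda_fit(train$features, train$class)
  structure(list(classifier_id = "mean_diff_lda", fit = fit), class = "linear_rule")
}

#' Linear support vector machine
#'
#' Soft-margin linear SVM (via \pkg{e1071}/libsvm) with cost parameter
#' `cost`, no feature scaling. Deterministic given the training data.
#'
#' @param train A [nested_data()] object containing both classes.
#' @param cost Positive soft-margin cost (default 1).
#' @return An object of class `"linear_rule"`.
#' @export
fit_linear_svm <- function(train, cost = 1) {
  if (!inherits(train, "nested_data")) stop("'train' must be a nested_data object")
  if (!is.finite(cost) || cost <= 0) stop("'cost' must be > 0")
  if (length(unique(train$class)) < 2L)
    stop("training data must contain both classes")
  fit <- e1071::svm(x = train$features, y = factor(train$class, levels = c(1L, 2L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  structure(list(classifier_id = "linear_svm", fit = fit), class = "linear_rule")
}

#' @export
predict.linear_rule <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$classifier_id == "mean_diff_lda") {
    .lda_predict(object$fit, newdata)
  } else {
    as.integer(as.character(stats::predict(object$fit, newdata)))
  }
}

#' Cross-validated correct classification rate
#'
#' Splits the data according to `cv`, trains the requested classifier on each
#' training fold and pools the held-out predictions into a single correct
#' classification rate (CCR): correctly classified test trials divided by the
#' total number of test trials. Pooling over trials (rather than averaging
#' fold CCRs) makes unequal fold sizes harmless; for balanced stratified folds
#' the two coincide.
#'
#' @param data A [nested_data()] object.
#' @param classifier `"mean_diff_lda"` (mean-difference rule, the default) or
#'   `"linear_svm"`.
#' @param cv A [cv_scheme()].
#' @param cost SVM cost parameter, ignored for `"mean_diff_lda"`.
#' @return An object of class `"ccr_result"`: list with `ccr`, `per_fold_ccr`,
#'   `classifier_id`, `cv`, `n_test_trials` and the fold assignment `folds`.
#' @export
#' @examples
#' dat <- generate_dataset(sim_params(d = 10, K = 4, N = 15,
#'                                    sigma_S = 0.5, seed = 3))
#' cross_validate(dat, "mean_diff_lda", cv_scheme("2fold", seed = 3))
cross_validate <- function(data, classifier = c("mean_diff_lda", "linear_svm"),
                           cv = cv_scheme(), cost = 1) {
  classifier <- match.arg(classifier)
  if (!inherits(data, "nested_data")) stop("'data' must be a nested_data object")
  if (!inherits(cv, "cv_scheme")) stop("'cv' must be a cv_scheme object")
  folds <- make_folds(data, cv)
  n_correct <- 0L; n_test <- 0L
  per_fold <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(data$features)), test_idx)
    cl_train <- data$class[train_idx]
    if (length(unique(cl_train)) < 2L)
      stop("a training fold contains only one class")
    xte <- data$features[test_idx, , drop = FALSE]
    pred <- if (classifier == "mean_diff_lda") {
      .lda_predict(.lda_fit(data$features[train_idx, , drop = FALSE], cl_train), xte)
    } else {
      train <- nested_data(data$features[train_idx, , drop = FALSE],
                           cl_train, data$subclass[train_idx], validate = FALSE)
      predict(fit_linear_svm(train, cost = cost), xte)
    }
    ok <- sum(pred == data$class[test_idx])
    per_fold[f] <- ok / length(test_idx)
    n_correct <- n_correct + ok
    n_test <- n_test + length(test_idx)
  }
  structure(list(ccr = n_correct / n_test, per_fold_ccr = per_fold,
                 classifier_id = classifier, cv = cv,
                 n_test_trials = n_test, folds = folds),
            class = "ccr_result")
}

#' @export
print.ccr_result <- function(x, ...) {
  cat(sprintf("CCR = %.4f (%s, %s, %d folds, %d test trials)\n",
              x$ccr, x$classifier_id, x$cv$kind, length(x$per_fold_ccr),
              x$n_test_trials))
  invisible(x)
}
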