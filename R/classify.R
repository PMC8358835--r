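#' Assemble a labeled feature set
#'
#' @param X samples x d numeric feature matrix.
#' @param labels per-sample class labels (coerced to factor).
#' @param feature_names optional column names.
#' @return a `feature_set` list with `X`, `labels`, `feature_names`.
#' @export
feature_set <- function(X, labels, feature_names = colnames(X)) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels))
    stop("X has ", nrow(X), " rows but ", length(labels), " labels")
  if (any(!is.finite(X))) stop("non-finite feature values")
  labels <- factor(labels)
  if (is.null(feature_names)) feature_names <- sprintf("f%d", seq_len(ncol(X)))
  colnames(X) <- feature_names
  structure(list(X = X, labels = labels, feature_names = feature_names),
            class = "feature_set")
}

as_feature_set <- function(fs) {
  if (inherits(fs, "feature_set")) fs else stop("expected a feature_set")
}

# ---- logistic regression with L2 penalty (one-vs-rest for multi-class) ----

logistic_nll_grad <- function(w, X1, yb, reg) {
  # X1 has an intercept column first; intercept unpenalized
  eta <- as.numeric(X1 %*% w)
  p <- 1 / (1 + exp(-eta))
  pen <- c(0, w[-1L])
  nll <- -sum(yb * eta - log1p(exp(eta))) + reg * sum(pen^2)
  g <- -crossprod(X1, yb - p)[, 1L] + 2 * reg * pen
  list(value = nll, grad = g)
}

fit_logistic_binary <- function(X, yb, reg) {
  X1 <- cbind(1, X)
  w0 <- numeric(ncol(X1))
  fn <- function(w) logistic_nll_grad(w, X1, yb, reg)$value
  gr <- function(w) logistic_nll_grad(w, X1, yb, reg)$grad
  opt <- stats::optim(w0, fn, gr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  opt$par
}

#' L2-regularized logistic regression classifier
#'
#' Binary model `p(y = 1 | x) = 1 / (1 + exp(-(b + w'x)))` fit by penalized
#' maximum likelihood: negative log-likelihood plus
#' `reg_strength * sum(w^2)` (the bias is not penalized). Multi-class
#' problems are handled one-vs-rest; prediction is the argmax of the
#' per-class linear scores, ties broken toward the lowest class index.
#'
#' @param features a [feature_set()] (assumed already standardized; the
#'   cross-validation harness z-scores with training-fold statistics).
#' @param reg_strength L2 penalty coefficient, > 0.
#' @return a `classifier_model` with `weights` (classes x d), `bias`,
#'   `classes`, `backend = "logistic_l2"`.
#' @export
fit_logistic_l2 <- function(features, reg_strength = 1) {
  fs <- as_feature_set(features)
  if (reg_strength <= 0) stop("reg_strength must be > 0")
  classes <- levels(droplevels(fs$labels))
  if (length(classes) < 2L) stop("need at least 2 classes, got ", length(classes))
  W <- t(vapply(classes, function(cl)
    fit_logistic_binary(fs$X, as.numeric(fs$labels == cl), reg_strength),
    numeric(ncol(fs$X) + 1L)))
  structure(list(weights = W[, -1L, drop = FALSE], bias = W[, 1L],
                 classes = classes, reg_strength = reg_strength,
                 backend = "logistic_l2"),
            class = "classifier_model")
}

#' Ridge classifier
#'
#' Least squares on one-hot class indicators with an L2 penalty on the
#' weights (intercept unpenalized, handled by centering); prediction is the
#' argmax of the linear scores.
#'
#' @inheritParams fit_logistic_l2
#' @param reg_strength L2 penalty, >= 0 (0 gives plain least squares).
#' @return a `classifier_model` with `backend = "ridge"`.
#' @export
fit_ridge <- function(features, reg_strength = 1) {
  fs <- as_feature_set(features)
  if (reg_strength < 0) stop("reg_strength must be >= 0")
  classes <- levels(droplevels(fs$labels))
  if (length(classes) < 2L) stop("need at least 2 classes, got ", length(classes))
  Y <- vapply(classes, function(cl) as.numeric(fs$labels == cl),
              numeric(nrow(fs$X)))
  xm <- colMeans(fs$X); ym <- colMeans(Y)
  Xc <- sweep(fs$X, 2L, xm)
  Yc <- sweep(Y, 2L, ym)
  d <- ncol(Xc)
  W <- solve(crossprod(Xc) + reg_strength * diag(d), crossprod(Xc, Yc))
  bias <- ym - as.numeric(xm %*% W)
  structure(list(weights = t(W), bias = bias, classes = classes,
                 reg_strength = reg_strength, backend = "ridge"),
            class = "classifier_model")
}

#' Linear SVM backend (delegated)
#'
#' A comparison baseline delegated to an external implementation
#' (`e1071::svm`, linear kernel, C = 1). Not re-implemented here; if the
#' `e1071` package is not installed this backend raises an informative
#' error.
#'
#' @inheritParams fit_logistic_l2
#' @param cost soft-margin cost C.
#' @return a `classifier_model` with `backend = "svm"`.
#' @export
fit_svm <- function(features, cost = 1) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("the 'svm' backend delegates to the e1071 package, which is not ",
         "installed; use backend 'logistic_l2' or 'ridge'")
  fs <- as_feature_set(features)
  model <- e1071::svm(fs$X, fs$labels, kernel = "linear", cost = cost,
                      scale = FALSE)
  structure(list(model = model, classes = levels(droplevels(fs$labels)),
                 backend = "svm"),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("<classifier_model:%s> %d classes\n", x$backend,
              length(x$classes)))
  invisible(x)
}

#' Predict class labels
#'
#' @param object a `classifier_model`.
#' @param newdata samples x d matrix on the same feature scale the model was
#'   fit on.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.classifier_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$backend == "svm")
    return(as.character(predict(object$model, newdata)))
  scores <- sweep(newdata %*% t(object$weights), 2L, object$bias, `+`)
  object$classes[apply(scores, 1L, which.max)]
}

fit_backend <- function(features, backend, reg_strength) {
  switch(backend,
         logistic_l2 = fit_logistic_l2(features, reg_strength),
         ridge = fit_ridge(features, reg_strength),
         svm = fit_svm(features),
         stop("unknown backend: ", backend))
}

#' Confusion matrix and derived metrics
#'
#' Rows of the confusion matrix are true classes, columns are predicted
#' classes. `precision_k = diag_k / colsum_k` (reported `NA` when class k
#' was never predicted, rather than 0), `recall_k = diag_k / rowsum_k`,
#' `accuracy = trace / total`.
#'
#' @param true_labels,predicted_labels equal-length label vectors; the class
#'   set is the union of both.
#' @return an `eval_report` list with `confusion`, `precision`, `recall`,
#'   `accuracy`.
#' @export
confusion_and_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors have different lengths")
  classes <- sort(unique(c(as.character(true_labels),
                           as.character(predicted_labels))),
                  method = "radix")  # locale-independent ordering
  tf <- factor(as.character(true_labels), levels = classes)
  pf <- factor(as.character(predicted_labels), levels = classes)
  confusion <- table(true = tf, predicted = pf)
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(true = classes, predicted = classes))
  diagv <- diag(confusion)
  colsum <- colSums(confusion); rowsum <- rowSums(confusion)
  precision <- ifelse(colsum > 0, diagv / colsum, NA_real_)
  recall <- ifelse(rowsum > 0, diagv / rowsum, NA_real_)
  structure(list(confusion = confusion,
                 precision = stats::setNames(precision, classes),
                 recall = stats::setNames(recall, classes),
                 accuracy = sum(diagv) / sum(confusion)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat(sprintf("accuracy: %.4f\n", x$accuracy))
  if (!is.null(x$mean_sd))
    cat(sprintf("over %d repeats: %.4f +/- %.4f\n",
                length(x$repeats), x$mean_sd[1L], x$mean_sd[2L]))
  invisible(x)
}

stratified_folds <- function(labels, folds) {
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop("class ", cl, " has ", length(idx),
           " samples, fewer than folds = ", folds)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

zscore_train_apply <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, `/`),
       test = sweep(sweep(test, 2L, mu), 2L, sdv, `/`))
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat the samples are partitioned into stratified folds (each
#' class split as evenly as possible); every sample is predicted exactly
#' once per repeat by a model trained on the remaining folds. Features are
#' z-scored with training-fold statistics only, so no information leaks
#' from the test fold. The confusion matrix aggregates all
#' `repeats * n` predictions (its row sums equal `repeats` times the true
#' class counts); the accuracy distribution over repeats gives the
#' mean +/- SD summary.
#'
#' @param features a [feature_set()].
#' @param backend `"logistic_l2"`, `"ridge"` or `"svm"`.
#' @param folds number of folds (default 5).
#' @param repeats number of independent repetitions (default 100).
#' @param seed integer; fixes the fold shuffles, making the report
#'   bit-reproducible.
#' @param reg_strength penalty passed to the backend.
#' @return an `eval_report` with `confusion`, `precision`, `recall`,
#'   `accuracy`, `repeats` (per-repeat accuracies) and `mean_sd`.
#' @export
cross_validate <- function(features, backend = "logistic_l2", folds = 5L,
                           repeats = 100L, seed = 1L, reg_strength = 1) {
  fs <- as_feature_set(features)
  labels <- droplevels(fs$labels)
  restore <- local_rng(seed)
  on.exit(restore())
  all_true <- character(0); all_pred <- character(0)
  rep_acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(labels, folds)
    pred <- character(length(labels))
    for (f in seq_len(folds)) {
      te <- fold_id == f
      zs <- zscore_train_apply(fs$X[!te, , drop = FALSE],
                               fs$X[te, , drop = FALSE])
      model <- fit_backend(feature_set(zs$train, labels[!te]), backend,
                           reg_strength)
      pred[te] <- predict(model, zs$test)
    }
    rep_acc[r] <- mean(pred == as.character(labels))
    all_true <- c(all_true, as.character(labels))
    all_pred <- c(all_pred, pred)
  }
  rep_out <- confusion_and_metrics(all_true, all_pred)
  rep_out$repeats <- rep_acc
  rep_out$mean_sd <- c(mean = mean(rep_acc), sd = stats::sd(rep_acc))
  rep_out
}

#' Single stratified holdout evaluation
#'
#' Splits the samples into a stratified training portion (default 80%) and a
#' verification portion (20%), fits once and reports metrics on the holdout.
#'
#' @inheritParams cross_validate
#' @param train_frac fraction of each class assigned to training.
#' @return an `eval_report`.
#' @export
evaluate_holdout <- function(features, backend = "logistic_l2",
                             train_frac = 0.8, seed = 1L, reg_strength = 1) {
  fs <- as_feature_set(features)
  labels <- droplevels(fs$labels)
  restore <- local_rng(seed)
  on.exit(restore())
  tr <- logical(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    ntr <- max(1L, floor(train_frac * length(idx)))
    tr[idx[sample.int(length(idx), ntr)]] <- TRUE
  }
  if (all(tr) || !any(tr)) stop("degenerate holdout split")
  zs <- zscore_train_apply(fs$X[tr, , drop = FALSE], fs$X[!tr, , drop = FALSE])
  model <- fit_backend(feature_set(zs$train, labels[tr]), backend,
                       reg_strength)
  pred <- predict(model, zs$test)
  confusion_and_metrics(as.character(labels[!tr]), pred)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(confusion = unclass(report$confusion),
              classes = colnames(report$confusion),
              precision = report$precision,
              recall = report$recall,
              accuracy = report$accuracy)
  if (!is.null(report$repeats)) {
    out$repeat_accuracies <- report$repeats
    out$mean_sd <- report$mean_sd
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
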