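# Cross-validated classification of reporter signatures: linear SVM,
# random forest, and a regularized (ridge-logistic) linear model, with
# per-fold ROC/AUC, multiclass confusion matrices, and recursive feature
# elimination. All randomness (fold assignment, forest bootstraps) flows
# from the `seed` argument.

paa_algorithms <- c("svm", "random_forest", "linear_model")

# Stratified fold assignment: within each class, samples are shuffled and
# dealt to folds round-robin. Uses the current RNG state.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Training-fold standardization (z-score per feature); zero-variance
# features are left unscaled. Applied before SVM / linear model fits only.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$mu), 2L, scaler$sd, "/")
}

needs_scaling <- function(algorithm) algorithm %in% c("svm", "linear_model")

glmnet_lambda <- 0.01

# glmnet insists on >= 2 columns; pad single-feature fits with a constant
# zero column (it attracts zero weight and is dropped from importances).
pad_glmnet <- function(x) {
  if (ncol(x) >= 2L) return(x)
  cbind(x, `..pad..` = 0)
}

fit_binary <- function(x, y, algorithm) {
  # y: factor with levels c("neg", "pos")
  switch(algorithm,
    svm = e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE),
    random_forest = randomForest::randomForest(x, y, ntree = 500L),
    linear_model = glmnet::glmnet(pad_glmnet(x), y, family = "binomial",
                                  alpha = 0,
                                  lambda = c(1, 0.1, glmnet_lambda),
                                  standardize = FALSE)
  )
}

score_binary <- function(model, x, algorithm) {
  # Higher score = more "pos". SVM decision values are oriented by parsing
  # the "first/second" class name attached to the decision column.
  switch(algorithm,
    svm = {
      pred <- stats::predict(model, x, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      if (identical(first, "pos")) dv[, 1] else -dv[, 1]
    },
    random_forest = stats::predict(model, x, type = "prob")[, "pos"],
    linear_model = as.numeric(stats::predict(model, pad_glmnet(x),
                                             s = glmnet_lambda,
                                             type = "link"))
  )
}

importance_binary <- function(model, x, algorithm) {
  imp <- switch(algorithm,
    svm = {
      w <- as.numeric(t(model$coefs) %*% model$SV)
      stats::setNames(abs(w), colnames(model$SV) %||% colnames(x))
    },
    random_forest = {
      im <- randomForest::importance(model)[, "MeanDecreaseGini"]
      stats::setNames(as.numeric(im), rownames(randomForest::importance(model)))
    },
    linear_model = {
      cf <- as.matrix(stats::coef(model, s = glmnet_lambda))
      stats::setNames(abs(cf[-1, 1]), rownames(cf)[-1])
    }
  )
  imp[colnames(x)]
}

fit_multiclass_linear <- function(x, y) {
  # glmnet warns about classes below 8 observations; expected for small
  # cross-validation folds, so silenced here.
  suppressWarnings(
    glmnet::glmnet(pad_glmnet(x), y, family = "multinomial", alpha = 0,
                   lambda = c(1, 0.1, glmnet_lambda), standardize = FALSE))
}

roc_curve_points <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c("neg", "pos"), direction = "<", quiet = TRUE)
  data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
}

binary_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c("neg", "pos"), direction = "<",
                                 quiet = TRUE)))
}

prepare_binary_labels <- function(classes, positive_class) {
  if (!positive_class %in% classes) {
    stop("positive class '", positive_class, "' not present", call. = FALSE)
  }
  if (length(unique(classes)) < 2L) {
    stop("classification needs at least 2 classes", call. = FALSE)
  }
  factor(ifelse(classes == positive_class, "pos", "neg"),
         levels = c("neg", "pos"))
}

#' Train and cross-validate a binary classifier
#'
#' Stratified k-fold cross-validation of a diagnostic classifier on the
#' reporter matrix: the positive class against all other samples. Features
#' are standardized on the training folds only for the SVM and linear
#' model; the random forest sees raw values. Per-fold AUC is computed on
#' the held-out samples with the ROC direction fixed, and the pooled
#' out-of-fold scores give the ROC curve. Identical inputs and seed yield
#' an identical report.
#'
#' @param ds A [reporter_dataset()].
#' @param algorithm `"svm"` (linear kernel), `"random_forest"`, or
#'   `"linear_model"` (ridge-regularized logistic regression).
#' @param positive_class Class label treated as positive.
#' @param folds Number of cross-validation folds (default 5); must not
#'   exceed the smaller class count.
#' @param seed Integer seed governing fold assignment and any model
#'   randomness.
#' @return An object of class `classifier_report`: `mean_auc`, `fold_auc`,
#'   `roc_points`, the out-of-fold score table `oof`, and the call
#'   parameters.
#' @export
train_classifier <- function(ds, algorithm = c("svm", "random_forest",
                                               "linear_model"),
                             positive_class, folds = 5L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  preserve_rng()
  x <- ds$values
  y <- prepare_binary_labels(ds$classes, positive_class)
  if (min(table(y)) < folds) {
    stop("`folds` exceeds the smaller class count (", min(table(y)), ")",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "cv_folds"))
  fold <- stratified_folds(as.character(y), folds)
  oof_score <- rep(NA_real_, nrow(x))
  fold_auc <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (needs_scaling(algorithm)) {
      scaler <- fit_scaler(xtr)
      xtr <- apply_scaler(xtr, scaler)
      xte <- apply_scaler(xte, scaler)
    }
    set.seed(substream_seed(seed, paste0("fit_fold", f)))
    model <- fit_binary(xtr, y[tr], algorithm)
    sc <- score_binary(model, xte, algorithm)
    oof_score[!tr] <- sc
    fold_auc[f] <- binary_auc(y[!tr], sc)
  }
  structure(
    list(algorithm = algorithm,
         positive_class = positive_class,
         cv = sprintf("stratified %d-fold", folds),
         folds = folds,
         fold_auc = fold_auc,
         mean_auc = mean(fold_auc),
         roc_points = roc_curve_points(y, oof_score),
         oof = data.frame(sample = rownames(x), truth = as.character(y),
                          score = oof_score, fold = fold,
                          stringsAsFactors = FALSE),
         seed = seed),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s, %s, positive = '%s'\n", x$algorithm,
              x$cv, x$positive_class))
  cat(sprintf("  mean AUC = %.3f (folds: %s)\n", x$mean_auc,
              paste(sprintf("%.3f", x$fold_auc), collapse = ", ")))
  invisible(x)
}

fit_multiclass <- function(x, y, algorithm) {
  switch(algorithm,
    svm = e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE),
    random_forest = randomForest::randomForest(x, y, ntree = 500L),
    linear_model = fit_multiclass_linear(x, y)
  )
}

predict_multiclass <- function(model, x, algorithm, levels) {
  cl <- switch(algorithm,
    svm = as.character(stats::predict(model, x)),
    random_forest = as.character(stats::predict(model, x)),
    linear_model = as.character(stats::predict(model, pad_glmnet(x),
                                               s = glmnet_lambda,
                                               type = "class"))
  )
  factor(cl, levels = levels)
}

#' Cross-validated multiclass classification
#'
#' Stratified k-fold cross-validation over three or more classes; the
#' out-of-fold predictions are aggregated into a class-by-class confusion
#' matrix (rows = truth, so row sums equal the per-class sample counts),
#' with per-class precision and recall.
#'
#' @inheritParams train_classifier
#' @return An object of class `multiclass_report`: `confusion` matrix,
#'   `accuracy`, `per_class` precision/recall table, `oof` predictions.
#' @export
evaluate_multiclass <- function(ds, algorithm = c("svm", "random_forest",
                                                  "linear_model"),
                                folds = 5L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  preserve_rng()
  x <- ds$values
  lev <- sort(unique(ds$classes))
  if (length(lev) < 3L) {
    stop("multiclass evaluation needs at least 3 classes; use train_classifier() for binary problems",
         call. = FALSE)
  }
  y <- factor(ds$classes, levels = lev)
  if (min(table(y)) < folds) {
    stop("`folds` exceeds the smallest class count (", min(table(y)), ")",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "cv_folds"))
  fold <- stratified_folds(ds$classes, folds)
  pred <- factor(rep(NA_character_, nrow(x)), levels = lev)
  for (f in seq_len(folds)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (needs_scaling(algorithm)) {
      scaler <- fit_scaler(xtr)
      xtr <- apply_scaler(xtr, scaler)
      xte <- apply_scaler(xte, scaler)
    }
    set.seed(substream_seed(seed, paste0("fit_fold", f)))
    model <- fit_multiclass(xtr, y[tr], algorithm)
    pred[!tr] <- predict_multiclass(model, xte, algorithm, lev)
  }
  confusion <- table(truth = y, predicted = pred)
  per_class <- data.frame(
    class = lev,
    recall = diag(confusion) / pmax(rowSums(confusion), 1L),
    precision = diag(confusion) / pmax(colSums(confusion), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(algorithm = algorithm, cv = sprintf("stratified %d-fold", folds),
         folds = folds, confusion = confusion,
         accuracy = sum(diag(confusion)) / sum(confusion),
         per_class = per_class,
         oof = data.frame(sample = rownames(x), truth = as.character(y),
                          predicted = as.character(pred), fold = fold,
                          stringsAsFactors = FALSE),
         seed = seed),
    class = "multiclass_report")
}

#' @export
print.multiclass_report <- function(x, ...) {
  cat(sprintf("<multiclass_report> %s, %s; accuracy = %.3f\n", x$algorithm,
              x$cv, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Recursive feature elimination over reporters
#'
#' Iteratively refits the classifier, recording the cross-validated AUC at
#' each panel size, and drops the reporter with the lowest model importance
#' (absolute linear weight for the SVM and linear model, Gini importance
#' for the random forest) until `n_keep` reporters remain. The final
#' ranking is the reverse elimination order: rank 1 is the most valuable
#' reporter. Ties in importance are broken by dropping the
#' lexicographically later reporter id.
#'
#' @inheritParams train_classifier
#' @param n_keep Number of reporters to retain (>= 1).
#' @return An object of class `rfe_result`: `ranking` (data frame of
#'   reporter and rank), `curve` (AUC versus panel size), algorithm and
#'   seed.
#' @export
recursive_feature_elimination <- function(ds, algorithm = c("svm",
                                                            "random_forest",
                                                            "linear_model"),
                                          positive_class, n_keep = 1L,
                                          folds = 5L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  preserve_rng()
  preserve_rng()
  k <- ncol(ds$values)
  if (n_keep < 1L || n_keep > k) {
    stop("`n_keep` must be between 1 and the number of reporters (", k, ")",
         call. = FALSE)
  }
  y <- prepare_binary_labels(ds$classes, positive_class)
  current <- colnames(ds$values)
  eliminated <- character(0)
  curve <- data.frame(n_features = integer(0), mean_auc = numeric(0))
  final_importance <- NULL
  repeat {
    sub <- ds
    sub$values <- ds$values[, current, drop = FALSE]
    rep_k <- train_classifier(sub, algorithm, positive_class, folds,
                              seed = substream_seed(seed,
                                                    paste0("size", length(current))))
    curve <- rbind(curve, data.frame(n_features = length(current),
                                     mean_auc = rep_k$mean_auc))
    x <- ds$values[, current, drop = FALSE]
    if (needs_scaling(algorithm)) x <- apply_scaler(x, fit_scaler(x))
    set.seed(substream_seed(seed, paste0("imp", length(current))))
    model <- fit_binary(x, y, algorithm)
    imp <- importance_binary(model, x, algorithm)
    if (length(current) <= n_keep) {
      final_importance <- imp
      break
    }
    worst <- min(imp)
    drop_id <- max(names(imp)[imp == worst])  # tie-break: later id goes
    eliminated <- c(eliminated, drop_id)
    current <- setdiff(current, drop_id)
  }
  kept_order <- names(sort(final_importance, decreasing = TRUE))
  ranking <- data.frame(
    reporter = c(kept_order, rev(eliminated)),
    rank = seq_len(k),
    stringsAsFactors = FALSE)
  structure(list(ranking = ranking, curve = curve, algorithm = algorithm,
                 positive_class = positive_class, n_keep = n_keep,
                 seed = seed),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %s, kept %d; top reporters: %s\n", x$algorithm,
              x$n_keep,
              paste(utils::head(x$ranking$reporter, 3), collapse = ", ")))
  invisible(x)
}

#' ROC plot for a classifier report
#'
#' @param report A [train_classifier()] result.
#' @param path Optional figure path; when given the plot is written there.
#' @return A ggplot object, invisibly when written to file.
#' @export
plot_roc <- function(report, path = NULL) {
  p <- ggplot2::ggplot(report$roc_points,
                       ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s, mean AUC = %.3f", report$algorithm,
                                  report$mean_auc)) +
    ggplot2::theme_classic()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 5, height = 4)
    return(invisible(p))
  }
  p
}
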