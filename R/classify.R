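# Integrated cancer classification: feature-block assembly (TSS
# methylation, copy ratios, cell proportions), train-only standardization
# and PCA reduction, random-forest / radial-SVM training with stratified
# cross-validation, ROC/AUC evaluation and permutation feature importance.

#' Stratified train/test split
#'
#' Disjoint, exhaustive split of sample indices. With stratification the
#' class proportions are preserved within rounding. The default
#' \code{train_fraction = 0.25} is the 1:3 train:test design.
#'
#' @param labels two-class vector, one entry per sample.
#' @param train_fraction fraction of samples assigned to training.
#' @param seed integer RNG seed; the same seed reproduces the split.
#' @param stratified split within each class (default TRUE).
#' @return list(train, test) of integer indices.
#' @export
split_cohort <- function(labels, train_fraction = 0.25, seed = 1,
                         stratified = TRUE) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) .stopf("need >= 2 samples per class")
  set.seed(seed)
  n <- length(labels)
  if (stratified) {
    # largest-remainder allocation so the total training size is
    # round(n * train_fraction) while class balance holds within rounding
    sizes <- table(labels)
    target <- round(n * train_fraction)
    base <- floor(sizes * train_fraction)
    rem <- sizes * train_fraction - base
    extra <- target - sum(base)
    if (extra > 0) {
      give <- order(-rem)[seq_len(extra)]
      base[give] <- base[give] + 1
    }
    train <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      n_tr <- base[[lv]]
      if (n_tr < 1 || n_tr >= length(idx))
        .stopf("class '%s' would have an empty train or test side", lv)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
  } else {
    n_tr <- round(n * train_fraction)
    train <- sort(sample.int(n, n_tr))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Fit a center/scale standardization on training data
#'
#' Column means and standard deviations are computed from the training
#' block only; zero-variance columns get scale 1 so they map to constant
#' zero rather than dividing by zero.
#'
#' @param train_block samples x features numeric matrix.
#' @return object of class \code{cfmeth_standardizer}: list(center, scale).
#' @export
fit_standardize <- function(train_block) {
  m <- as.matrix(train_block)
  if (nrow(m) < 2) .stopf("need >= 2 training samples")
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale),
            class = "cfmeth_standardizer")
}

#' Apply a fitted standardization to a feature block
#'
#' @param transform a \code{cfmeth_standardizer} (training statistics only
#'   are used, so applying to held-out data leaks nothing).
#' @param block samples x features matrix with the same columns.
#' @return standardized matrix.
#' @export
apply_standardize <- function(transform, block) {
  m <- as.matrix(block)
  sweep(sweep(m, 2, transform$center), 2, transform$scale, "/")
}

#' Fit a PCA reduction on standardized training data
#'
#' Retains the minimal prefix of principal components whose cumulative
#' explained variance reaches \code{variance_target} (default 95\%).
#' Loading signs follow the convention that each component's
#' largest-magnitude loading is positive, making the reduction
#' reproducible across platforms.
#'
#' @param train_block standardized samples x features matrix.
#' @param variance_target cumulative variance fraction to reach.
#' @return object of class \code{cfmeth_pca}: list(rotation, n_components,
#'   sdev).
#' @export
pca_reduce <- function(train_block, variance_target = 0.95) {
  m <- as.matrix(train_block)
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev / sum(ev)
  k <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(rotation = rot, n_components = k, sdev = pc$sdev),
            class = "cfmeth_pca")
}

#' Apply a fitted PCA reduction
#'
#' @param transform a \code{cfmeth_pca} fitted on training data.
#' @param block standardized samples x features matrix.
#' @return samples x components score matrix.
#' @export
apply_pca <- function(transform, block) {
  as.matrix(block) %*% transform$rotation
}

#' Assemble classifier features from preprocessed blocks
#'
#' Horizontal concatenation of the selected blocks: PCA-reduced TSS
#' methylation ("meth"), PCA-reduced copy ratios ("cnv"), and cell-type
#' proportions ("props") with one cell type dropped to break the simplex
#' collinearity (proportions sum to 1, so one column is redundant).
#'
#' @param blocks named list with any of \code{meth}, \code{cnv},
#'   \code{props} (samples x features matrices, consistent row order).
#' @param include character subset of blocks to use.
#' @param drop_cell_type cell type (column of \code{props}) to exclude.
#' @return samples x features matrix.
#' @export
assemble_features <- function(blocks, include = c("meth", "cnv", "props"),
                              drop_cell_type = NULL) {
  include <- intersect(include, names(blocks))
  if (length(include) == 0L) .stopf("no feature blocks selected")
  ns <- vapply(blocks[include], nrow, integer(1))
  if (length(unique(ns)) != 1L) .stopf("blocks have inconsistent sample sets")
  parts <- lapply(include, function(b) {
    m <- as.matrix(blocks[[b]])
    if (is.null(colnames(m))) colnames(m) <- sprintf("f%d", seq_len(ncol(m)))
    if (b == "props" && !is.null(drop_cell_type)) {
      if (!drop_cell_type %in% colnames(m))
        .stopf("cell type '%s' not found in proportions block", drop_cell_type)
      m <- m[, setdiff(colnames(m), drop_cell_type), drop = FALSE]
    }
    colnames(m) <- paste(b, colnames(m), sep = ".")
    m
  })
  do.call(cbind, parts)
}

.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_model <- function(features, labels, model, params, seed) {
  set.seed(seed)
  if (model == "random_forest") {
    randomForest::randomForest(x = features, y = labels,
                               mtry = params$mtry, ntree = 500)
  } else {
    e1071::svm(x = features, y = labels, kernel = "radial",
               cost = params$cost, gamma = params$gamma,
               probability = TRUE)
  }
}

.predict_scores <- function(fit, features, positive) {
  features <- as.matrix(features)
  if (inherits(fit, "randomForest")) {
    stats::predict(fit, features, type = "prob")[, positive]
  } else {
    pr <- stats::predict(fit, features, probability = TRUE)
    attr(pr, "probabilities")[, positive]
  }
}

#' Train a cancer classifier with cross-validated hyperparameters
#'
#' Fits a random forest or radial-kernel SVM on the assembled features.
#' Hyperparameters (mtry for the forest; cost and gamma for the SVM) are
#' chosen by stratified k-fold cross-validation maximizing AUC, then the
#' winning setting is refitted on all training data. The seed fixes fold
#' assignment and model randomness.
#'
#' @param features samples x features matrix (training set).
#' @param labels two-class vector; the second factor level is the positive
#'   (case) class.
#' @param model "random_forest" or "svm_radial".
#' @param cv_folds number of CV folds (default 5).
#' @param seed integer RNG seed.
#' @return object of class \code{cfmeth_classifier}: list(model, fit,
#'   best_params, cv_results, levels, positive).
#' @export
train_classifier <- function(features, labels,
                             model = c("random_forest", "svm_radial"),
                             cv_folds = 5, seed = 1) {
  model <- match.arg(model)
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) .stopf("labels must have exactly 2 classes")
  if (any(table(labels) < cv_folds))
    .stopf("need >= %d samples per class for %d-fold CV", cv_folds, cv_folds)
  positive <- levels(labels)[2L]
  p <- ncol(features)
  grid <- if (model == "random_forest") {
    data.frame(mtry = unique(pmax(1, pmin(p, floor(sqrt(p) * c(0.5, 1, 2))))))
  } else {
    expand.grid(cost = c(0.25, 1, 4), gamma = (1 / p) * c(0.5, 1, 2))
  }
  set.seed(seed)
  fold <- .stratified_folds(labels, cv_folds)
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    scores <- rep(NA_real_, length(labels))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- .fit_model(features[tr, , drop = FALSE], droplevels(labels[tr]),
                        model, as.list(grid[g, , drop = FALSE]),
                        seed = .stage_seed(seed, sprintf("cv%d_%d", g, f)))
      scores[!tr] <- .predict_scores(fit, features[!tr, , drop = FALSE],
                                     positive)
    }
    cv_auc[g] <- auc_score(scores, labels, positive = positive)
  }
  best <- which.max(cv_auc)
  fit <- .fit_model(features, labels, model,
                    as.list(grid[best, , drop = FALSE]),
                    seed = .stage_seed(seed, "final"))
  structure(list(model = model, fit = fit,
                 best_params = as.list(grid[best, , drop = FALSE]),
                 cv_results = cbind(grid, cv_auc = cv_auc),
                 levels = levels(labels), positive = positive,
                 fold_assignment = fold),
            class = "cfmeth_classifier")
}

#' @export
print.cfmeth_classifier <- function(x, ...) {
  cat(sprintf("%s classifier (positive class: %s)\n",
              ifelse(x$model == "random_forest", "Random forest",
                     "Radial SVM"), x$positive))
  cat("best CV AUC:", format(max(x$cv_results$cv_auc), digits = 3),
      "at", paste(names(x$best_params), unlist(x$best_params),
                  sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict case scores
#'
#' @param object a \code{cfmeth_classifier}.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return numeric vector of positive-class scores in [0, 1].
#' @export
predict.cfmeth_classifier <- function(object, newdata, ...) {
  .predict_scores(object$fit, newdata, object$positive)
}

#' ROC curve and AUC on a held-out test set
#'
#' AUC is the Mann-Whitney statistic with midrank tie handling; ROC points
#' are produced at every distinct score threshold.
#'
#' @param model a \code{cfmeth_classifier}, or a numeric score vector.
#' @param test_features samples x features matrix (ignored when scores are
#'   passed directly).
#' @param test_labels two-class vector for the test samples.
#' @param positive positive class (defaults to the model's).
#' @return object of class \code{cfmeth_roc}: list(points, auc, scores).
#' @export
evaluate_roc <- function(model, test_features = NULL, test_labels,
                         positive = NULL) {
  if (inherits(model, "cfmeth_classifier")) {
    scores <- predict(model, test_features)
    if (is.null(positive)) positive <- model$positive
  } else {
    scores <- as.numeric(model)
  }
  labels <- as.factor(test_labels)
  if (nlevels(droplevels(labels)) != 2L)
    .stopf("test labels must contain both classes")
  if (is.null(positive)) positive <- levels(labels)[2L]
  auc <- auc_score(scores, labels, positive = positive)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  is_pos <- labels == positive
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !is_pos) / sum(!is_pos),
      tpr = sum(pred & is_pos) / sum(is_pos))
  }, numeric(2)))
  structure(list(points = data.frame(threshold = thr, fpr = pts[, "fpr"],
                                     tpr = pts[, "tpr"]),
                 auc = auc, scores = scores),
            class = "cfmeth_roc")
}

#' @export
print.cfmeth_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f over %d test samples\n", x$auc,
              length(x$scores)))
  invisible(x)
}

#' @export
plot.cfmeth_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Permutation feature importance
#'
#' Model-agnostic importance: each feature column is permuted
#' \code{n_repeats} times and the mean drop in AUC (relative to the
#' unpermuted AUC on the same data) is reported. Features are returned in
#' descending importance, ties broken by feature index, so the measure is
#' comparable between the forest and the SVM.
#'
#' @param model a \code{cfmeth_classifier}.
#' @param features samples x features matrix.
#' @param labels two-class vector.
#' @param n_repeats permutations per feature (default 10).
#' @param seed integer RNG seed.
#' @return data.frame (feature, importance) sorted by decreasing
#'   importance.
#' @export
feature_importance <- function(model, features, labels, n_repeats = 10,
                               seed = 1) {
  features <- as.matrix(features)
  base <- auc_score(predict(model, features), labels,
                    positive = model$positive)
  set.seed(seed)
  imp <- vapply(seq_len(ncol(features)), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      perm <- features
      perm[, j] <- sample(perm[, j])
      base - auc_score(predict(model, perm), labels,
                       positive = model$positive)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  nm <- colnames(features)
  if (is.null(nm)) nm <- sprintf("f%d", seq_len(ncol(features)))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = nm[ord], importance = imp[ord],
             stringsAsFactors = FALSE)
}
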