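# Feature assembly, train-only preprocessing, classifiers and evaluation.

test_that("stratified splits are disjoint, exhaustive and balanced", {
  labels <- rep(c("case", "control"), c(50, 34))
  sp <- split_cohort(labels, train_fraction = 0.25, seed = 3)
  expect_length(sp$train, 21L)   # 1:3 train:test on 84 samples
  expect_length(sp$test, 63L)
  expect_setequal(c(sp$train, sp$test), 1:84)
  sp2 <- split_cohort(rep(c("a", "b"), each = 5), 0.5, seed = 1)
  expect_length(sp2$train, 5L)
  expect_true(sum(sp2$train <= 5) %in% 2:3)  # class balance within rounding
  expect_identical(split_cohort(labels, 0.25, seed = 9),
                   split_cohort(labels, 0.25, seed = 9))
  expect_error(split_cohort(c("a", "a", "b"), 0.25), ">= 2 samples")
})

test_that("standardization uses training statistics only, with a zero-variance guard", {
  tr <- fit_standardize(matrix(c(1, 2, 3), ncol = 1))
  z <- apply_standardize(tr, matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  # constant column maps to zeros instead of dividing by zero
  trc <- fit_standardize(matrix(5, 4, 1))
  expect_equal(as.numeric(apply_standardize(trc, matrix(5, 4, 1))),
               rep(0, 4))
  # applying to held-out data uses the train center/scale, not its own
  set.seed(2)
  train <- matrix(rnorm(40, 10, 2), 20, 2)
  test <- matrix(rnorm(10, 0, 1), 5, 2)
  f <- fit_standardize(train)
  expect_equal(f$center, colMeans(train))
  zt <- apply_standardize(f, test)
  expect_equal(zt, sweep(sweep(test, 2, colMeans(train)), 2,
                         apply(train, 2, sd), "/"))
})

test_that("PCA retains the minimal prefix reaching the variance target", {
  set.seed(4)
  base <- rnorm(30)
  dup <- cbind(base, 2 * base)          # rank 1: one component suffices
  expect_equal(pca_reduce(dup)$n_components, 1L)
  # exactly equal singular values: every component explains 1/10
  q <- qr.Q(qr(matrix(rnorm(400), 40, 10)))
  expect_equal(pca_reduce(q, 0.95)$n_components, 10L)
  expect_equal(pca_reduce(q, 0.55)$n_components, 6L)
  # sign convention: the largest-magnitude loading is positive
  rot <- pca_reduce(matrix(rnorm(200), 40, 5))$rotation
  for (j in seq_len(ncol(rot)))
    expect_gt(rot[which.max(abs(rot[, j])), j], 0)
})

test_that("feature assembly concatenates blocks and drops one cell type", {
  n <- 6
  blocks <- list(meth = matrix(1, n, 4), cnv = matrix(2, n, 3),
                 props = matrix(1 / 7, n, 7,
                                dimnames = list(NULL, paste0("t", 1:7))))
  all3 <- assemble_features(blocks, drop_cell_type = "t7")
  expect_equal(ncol(all3), 4 + 3 + 6)
  expect_false(any(grepl("t7", colnames(all3))))
  expect_equal(ncol(assemble_features(blocks, include = "meth")), 4)
  expect_error(assemble_features(list(meth = matrix(1, 3, 2),
                                      props = matrix(1, 4, 2))),
               "inconsistent")
  expect_error(assemble_features(blocks, drop_cell_type = "t9"), "not found")
})

test_that("classifiers separate separable data, are seed-deterministic and reject degenerate labels", {
  set.seed(9)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- factor(rep(c("control", "case"), 30), levels = c("control", "case"))
  X[y == "case", 1] <- X[y == "case", 1] + 6
  for (model in c("random_forest", "svm_radial")) {
    m <- train_classifier(X, y, model, cv_folds = 5, seed = 11)
    expect_gte(max(m$cv_results$cv_auc), 0.95)
    m2 <- train_classifier(X, y, model, cv_folds = 5, seed = 11)
    expect_identical(m$fold_assignment, m2$fold_assignment)
    expect_identical(m$best_params, m2$best_params)
  }
  expect_error(train_classifier(X, factor(rep("a", 60)), "random_forest"),
               "2 classes")
})

test_that("AUC equals the pair-counting oracle and handles ties by midranks", {
  expect_equal(auc_score(c(0.9, 0.8, 0.1, 0.2), c("c", "c", "n", "n"),
                         positive = "c"), 1.0)
  expect_equal(auc_score(rep(0.5, 6), rep(c("c", "n"), 3), positive = "c"), 0.5)
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.3), c("c", "n", "c", "n"),
                         positive = "c"), 3 / 4)
  set.seed(13)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    scores <- round(runif(n), 2)   # rounded scores force ties
    labels <- sample(c("case", "ctrl"), n, TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_score(scores, labels, positive = "case"),
                 oracle_auc(scores, labels, "case"))
  }
})

test_that("ROC evaluation reports the curve endpoints and errors on one-class tests", {
  r <- evaluate_roc(c(0.9, 0.8, 0.1, 0.2), test_labels = c("b", "b", "a", "a"),
                    positive = "b")
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_error(evaluate_roc(c(0.2, 0.4), test_labels = c("a", "a")),
               "both classes")
})

test_that("permutation importance ranks the separating feature first and noise near zero", {
  set.seed(17)
  X <- matrix(rnorm(80 * 4), 80, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- factor(rep(c("control", "case"), 40), levels = c("control", "case"))
  X[y == "case", 2] <- X[y == "case", 2] + 5
  m <- train_classifier(X, y, "random_forest", seed = 19)
  imp <- feature_importance(m, X, y, n_repeats = 5, seed = 21)
  expect_equal(imp$feature[1], "f2")
  expect_lt(max(abs(imp$importance[imp$feature != "f2"])), 0.15)
})
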