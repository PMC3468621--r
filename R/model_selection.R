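# Fixed held-out test evaluation, stratified 10-fold CV grid search, and the
# overall-accuracy metric.
#
# Evaluation protocol: a fixed, balanced test set is drawn once per study
# seed; training sets of the requested size are drawn (balanced, seeded per
# iteration) from the remaining subjects, so no training draw ever touches
# the test set. Hyperparameters (lambda for RLR, C for the SVM) are chosen by
# 10-fold cross-validated grid search maximizing mean fold accuracy; the
# least-squares classifier has no hyperparameter and is fitted on the whole
# training set directly.

#' Default hyperparameter grids
#'
#' The reference grids span null-model to near-unregularized regimes:
#' 25 log-spaced lambdas in 10^\[-4, 1\] for RLR and 21 powers of two in
#' 2^\[-10, 10\] for the SVM cost.
#' @return a list with `lambda` and `C`.
#' @export
default_grids <- function() {
  list(lambda = 10^seq(-4, 1, length.out = 25),
       C = 2^seq(-10, 10, length.out = 21))
}

#' Draw a train/test split plan
#'
#' @param labels integer 0/1 labels of the full cohort.
#' @param n_test_per_class size of each class's share of the fixed test set.
#' @param sample_size total training size (must be even; balanced classes).
#' @param study_seed seed fixing the test set (one draw per study).
#' @param iteration_seed seed for this iteration's training draw.
#' @return object of class `split_plan`: `test_ids`, `train_ids` (integer
#'   row indices into the cohort), `sample_size`.
#' @export
make_split <- function(labels, n_test_per_class, sample_size, study_seed,
                       iteration_seed) {
  labels <- as.integer(labels)
  if (sample_size %% 2L != 0L) stop("sample_size must be even (balanced classes)")
  idx0 <- which(labels == 0L)
  idx1 <- which(labels == 1L)
  need <- n_test_per_class + sample_size / 2
  if (length(idx0) < need || length(idx1) < need) {
    stop(sprintf("insufficient subjects: need %d per class, have %d CN / %d AD",
                 need, length(idx0), length(idx1)))
  }
  test_ids <- with_seed(study_seed, {
    sort(c(sample(idx0, n_test_per_class), sample(idx1, n_test_per_class)))
  })
  pool0 <- setdiff(idx0, test_ids)
  pool1 <- setdiff(idx1, test_ids)
  train_ids <- with_seed(iteration_seed, {
    sort(c(sample(pool0, sample_size / 2), sample(pool1, sample_size / 2)))
  })
  structure(list(test_ids = test_ids, train_ids = train_ids,
                 sample_size = as.integer(sample_size)),
            class = "split_plan")
}

#' Confusion counts with AD (label 1) as the positive class
#'
#' @param truth integer 0/1 true labels.
#' @param predicted integer 0/1 predicted labels.
#' @return object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  structure(list(TP = sum(truth == 1L & predicted == 1L),
                 TN = sum(truth == 0L & predicted == 0L),
                 FP = sum(truth == 0L & predicted == 1L),
                 FN = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

#' Overall classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts a `confusion_counts`.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop("empty confusion counts")
  (counts$TP + counts$TN) / tot
}

#' Stratified fold assignment
#' @keywords internal
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

fit_method <- function(method, X, y, param, ...) {
  switch(method,
    rlr = fit_rlr(X, y, lambda = param, ...),
    svm = {
      Xs <- X
      attr(Xs, "standardized") <- TRUE  # suppress the kernel warning in folds
      fit_svm(linear_kernel(Xs), y, C = param, X_train = X, ...)
    },
    stop("unknown method: ", method)
  )
}

#' 10-fold cross-validated grid search for one hyperparameter
#'
#' For each grid value, the classifier is trained on 9/10 of the training
#' data and scored on the held-out fold, rotating through all 10 folds
#' (stratified so both classes appear in every fold). The value maximizing
#' mean fold accuracy wins; exact ties break toward stronger regularization
#' (larger lambda, smaller C). The winner is refitted on the full training
#' data.
#'
#' @param X_train standardized training feature matrix.
#' @param y_train integer 0/1 labels.
#' @param method `"rlr"` or `"svm"`.
#' @param grid numeric vector of candidate lambda (rlr) or C (svm) values;
#'   defaults to [default_grids()].
#' @param k number of folds.
#' @param seed seed for the fold assignment.
#' @param ... passed through to the fitting routine.
#' @return object of class `cv_result`: `grid`, `fold_accuracies`
#'   (grid x k matrix), `mean_accuracy`, `selected_value`,
#'   `mean_accuracy_at_selected`, `model` (refit on all training data).
#' @export
kfold_grid_search <- function(X_train, y_train, method = c("rlr", "svm"),
                              grid = NULL, k = 10, seed = 1L, alpha = 0.001,
                              ...) {
  method <- match.arg(method)
  y_train <- as.integer(y_train)
  stopifnot(is.matrix(X_train), nrow(X_train) == length(y_train))
  if (nrow(X_train) < k) stop("fewer training subjects than folds")
  if (is.null(grid)) {
    grid <- if (method == "rlr") default_grids()$lambda else default_grids()$C
  }
  folds <- stratified_folds(y_train, k, seed)
  if (any(tapply(y_train, folds, function(v) length(unique(v))) < 2L)) {
    stop("a fold lost one of the classes; use fewer folds")
  }
  acc <- matrix(NA_real_, length(grid), k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    te <- !tr
    if (method == "rlr") {
      # one penalty path per fold: the backend fits the whole grid at once
      lam_sorted <- sort(grid, decreasing = TRUE)
      Xf <- X_train[tr, , drop = FALSE]
      # fold fits only rank grid values; glmnet's small-class warning is
      # routine at fold sizes and not actionable here
      fit <- suppressWarnings(
        glmnet::glmnet(if (ncol(Xf) == 1L) cbind(Xf, 0) else Xf,
                       factor(y_train[tr], levels = c(0, 1)),
                       family = "binomial", alpha = alpha,
                       lambda = lam_sorted, standardize = FALSE))
      Xe <- X_train[te, , drop = FALSE]
      eta <- stats::predict(fit, if (ncol(Xe) == 1L) cbind(Xe, 0) else Xe,
                            type = "link")
      for (g in seq_along(grid)) {
        col <- which(lam_sorted == grid[g])[1]
        pred <- as.integer(eta[, col] >= 0)
        acc[g, fold] <- mean(pred == y_train[te])
      }
    } else {
      Xf <- X_train[tr, , drop = FALSE]
      attr(Xf, "standardized") <- TRUE
      Kf <- linear_kernel(Xf)
      Kc <- X_train[te, , drop = FALSE] %*% t(Xf)
      ord <- order(grid)  # ascending C for feasible warm starts
      warm <- NULL
      for (g in ord) {
        m <- fit_svm(Kf, y_train[tr], C = grid[g], check_psd = FALSE,
                     warm_alpha = warm, ...)
        warm <- m$alpha
        pred <- predict(m, K_cross = Kc)$label
        acc[g, fold] <- mean(pred == y_train[te])
      }
    }
  }
  mean_acc <- rowMeans(acc)
  best <- max(mean_acc)
  cands <- which(mean_acc >= best - 1e-12)
  sel <- if (method == "rlr") {
    cands[which.max(grid[cands])]   # larger lambda = more regularized
  } else {
    cands[which.min(grid[cands])]   # smaller C = more regularized
  }
  model <- if (method == "rlr") {
    fit_rlr(X_train, y_train, lambda = grid[sel], alpha = alpha)
  } else {
    fit_method("svm", X_train, y_train, grid[sel], ...)
  }
  structure(list(grid = grid, fold_accuracies = acc, mean_accuracy = mean_acc,
                 selected_value = grid[sel],
                 mean_accuracy_at_selected = mean_acc[sel],
                 method = method, model = model),
            class = "cv_result")
}

#' Evaluate a fitted model on the held-out test set
#'
#' Refuses to score subjects that were seen in training (leakage guard, by
#' row name when both matrices carry subject ids).
#'
#' @param model an `lrc_model`, `rlr_model` or `svm_model`.
#' @param X_test standardized test features.
#' @param y_test integer 0/1 labels.
#' @param train_ids optional character ids of the training subjects; defaults
#'   to the rownames of the model's stored training matrix.
#' @return list with `counts` (a `confusion_counts`), `accuracy`,
#'   `predictions`.
#' @export
evaluate_on_test <- function(model, X_test, y_test, train_ids = NULL) {
  if (is.null(train_ids) && !is.null(model$X_train)) {
    train_ids <- rownames(model$X_train)
  }
  if (!is.null(train_ids) && !is.null(rownames(X_test))) {
    overlap <- intersect(train_ids, rownames(X_test))
    if (length(overlap) > 0) {
      stop("test set contains training subjects: ",
           paste(utils::head(overlap, 5), collapse = ", "))
    }
  }
  pred <- if (inherits(model, "rlr_model")) {
    predict(model, X_test)
  } else {
    predict(model, X_new = X_test)
  }
  counts <- confusion_counts(y_test, pred$label)
  list(counts = counts, accuracy = accuracy(counts), predictions = pred)
}
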