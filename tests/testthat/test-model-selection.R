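# Splits, CV grid search, confusion counts, accuracy.

test_that("splits are balanced, disjoint, and reproducible", {
  labels <- rep(0:1, each = 100)
  s <- make_split(labels, n_test_per_class = 25, sample_size = 40,
                  study_seed = 5, iteration_seed = 9)
  expect_length(s$test_ids, 50)
  expect_length(s$train_ids, 40)
  expect_equal(sum(labels[s$test_ids]), 25)
  expect_equal(sum(labels[s$train_ids]), 20)
  expect_length(intersect(s$test_ids, s$train_ids), 0)
  s2 <- make_split(labels, 25, 40, study_seed = 5, iteration_seed = 9)
  expect_identical(s, s2)
  # the test set is fixed by the study seed across iterations
  s3 <- make_split(labels, 25, 40, study_seed = 5, iteration_seed = 10)
  expect_identical(s3$test_ids, s$test_ids)
  expect_false(identical(s3$train_ids, s$train_ids))
  expect_error(make_split(labels, 80, 60, 1, 1), "insufficient")
  expect_error(make_split(labels, 10, 31, 1, 1), "even")
})

test_that("no training draw ever intersects the fixed test set", {
  labels <- rep(0:1, each = 80)
  test_ids <- make_split(labels, 25, 20, 3, 1)$test_ids
  for (it in 1:100) {
    s <- make_split(labels, 25, 60, study_seed = 3, iteration_seed = 1000 + it)
    expect_identical(s$test_ids, test_ids)
    expect_length(intersect(s$train_ids, s$test_ids), 0)
  }
})

test_that("accuracy implements (TP+TN)/total with label symmetry", {
  expect_equal(accuracy(confusion_counts(rep(c(1, 0), c(50, 50)),
                                         rep(c(1, 0), c(50, 50)))), 1.0)
  c1 <- structure(list(TP = 40, TN = 45, FP = 5, FN = 10),
                  class = "confusion_counts")
  expect_equal(accuracy(c1), 0.85)
  c2 <- structure(list(TP = 45, TN = 40, FP = 10, FN = 5),
                  class = "confusion_counts")
  expect_equal(accuracy(c2), accuracy(c1))
  expect_error(accuracy(structure(list(TP = 0, TN = 0, FP = 0, FN = 0),
                                  class = "confusion_counts")), "empty")
  # counts identify AD (label 1) as positive
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc[c("TP", "FN", "FP", "TN")]),
               c(TP = 1, FN = 1, FP = 1, TN = 1))
})

test_that("grid search selects by mean fold accuracy with the stated tie rule", {
  p <- random_problem(50, 5, delta = 3, seed = 60)  # strongly separated
  cv <- kfold_grid_search(p$X, p$y, "rlr", grid = c(1e6, 0.01), seed = 4)
  expect_equal(cv$selected_value, 0.01)  # null model scores ~ 0.5
  expect_gt(cv$mean_accuracy_at_selected, 0.8)
  expect_equal(dim(cv$fold_accuracies), c(2, 10))

  one <- kfold_grid_search(p$X, p$y, "svm", grid = 1, seed = 4)
  expect_equal(one$selected_value, 1)

  # exact tie -> more regularized value (larger lambda / smaller C)
  p0 <- random_problem(40, 3, delta = 0, seed = 61)
  cv_tie <- kfold_grid_search(p0$X, p0$y, "rlr", grid = c(1e6, 1e7), seed = 2)
  expect_equal(cv_tie$selected_value, 1e7)
  cv_svm <- kfold_grid_search(p0$X, p0$y, "svm", grid = c(1e-4, 2e-4), seed = 2)
  expect_equal(cv_svm$selected_value, 1e-4)
})

test_that("stratified folds keep both classes everywhere", {
  y <- rep(c(0, 1), c(12, 8))
  folds <- voxelmvpa:::stratified_folds(y, 4, seed = 1)
  for (f in 1:4) {
    expect_setequal(unique(y[folds == f]), c(0, 1))
  }
  expect_error(kfold_grid_search(matrix(rnorm(10), 5), c(0, 0, 0, 0, 1),
                                 "rlr", grid = 1, k = 5), "fold")
})

test_that("evaluate_on_test scores models and guards against leakage", {
  p <- random_problem(60, 8, delta = 2, seed = 62)
  tr <- 1:40; te <- 41:60
  Xtr <- p$X[tr, ]; attr(Xtr, "standardized") <- TRUE
  Xte <- p$X[te, ]; attr(Xte, "standardized") <- TRUE
  m <- fit_lrc(linear_kernel(Xtr), p$y[tr], X_train = Xtr)
  ev <- evaluate_on_test(m, Xte, p$y[te])
  expect_equal(ev$accuracy, accuracy(ev$counts))
  expect_equal(ev$accuracy, mean(ev$predictions$label == p$y[te]))
  # scoring rows seen in training is refused
  expect_error(evaluate_on_test(m, Xtr[1:3, ], p$y[1:3]), "training subjects")
})

test_that("constant-classifier accuracies land at chance on balanced tests", {
  truth <- rep(0:1, each = 25)
  always1 <- confusion_counts(truth, rep(1L, 50))
  expect_equal(accuracy(always1), 0.5)
  expect_equal(always1$FP, 25)
})
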