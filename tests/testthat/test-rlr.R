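# Elastic-net regularized logistic regression.

test_that("huge penalty gives the null model exactly", {
  p <- random_problem(40, 6, seed = 1)  # balanced labels
  for (backend in c("cd", "glmnet")) {
    m <- fit_rlr(p$X, p$y, lambda = 1e6, alpha = 0.001, backend = backend)
    expect_equal(max(abs(m$coefficients)), 0)
    expect_equal(m$intercept, qlogis(mean(p$y)), tolerance = 1e-8)
  }
})

test_that("lambda = 0 matches a generic convex-optimizer oracle", {
  set.seed(44)
  n <- 100
  X <- matrix(rnorm(n * 2), n)
  y <- rbinom(n, 1, plogis(1.5 * X[, 1] - X[, 2]))
  attr(X, "standardized") <- TRUE
  obj <- function(par) rlr_objective_value(par[1], par[-1], X, y, 0, 0.001)
  oracle <- optim(rep(0, 3), obj, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-14))$par
  for (backend in c("cd", "glmnet")) {
    m <- fit_rlr(X, y, lambda = 0, backend = backend)
    expect_lt(max(abs(c(m$intercept, m$coefficients) - oracle)), 1e-4)
  }
})

test_that("penalized fits match the oracle and both backends agree", {
  set.seed(45)
  n <- 120; d <- 5
  X <- matrix(rnorm(n * d), n)
  y <- rbinom(n, 1, plogis(X %*% c(1, -1, 0.5, 0, 0)))
  attr(X, "standardized") <- TRUE
  for (prm in list(c(0.05, 0.001), c(0.02, 0.5))) {
    lam <- prm[1]; al <- prm[2]
    obj <- function(par) rlr_objective_value(par[1], par[-1], X, y, lam, al)
    oracle <- optim(rep(0, d + 1), obj, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))$par
    m_cd <- fit_rlr(X, y, lam, al, backend = "cd")
    m_gl <- fit_rlr(X, y, lam, al, backend = "glmnet")
    expect_lt(max(abs(c(m_cd$intercept, m_cd$coefficients) - oracle)), 1e-4)
    expect_lt(max(abs(m_cd$coefficients - m_gl$coefficients)), 1e-4)
  }
})

test_that("KKT stationarity holds at alpha = 1 for every nonzero coefficient", {
  set.seed(46)
  n <- 80; d <- 20
  X <- matrix(rnorm(n * d), n)
  y <- rbinom(n, 1, plogis(X %*% c(rep(1, 3), rep(0, d - 3))))
  attr(X, "standardized") <- TRUE
  for (lam in c(0.005, 0.02, 0.08)) {
    m <- fit_rlr(X, y, lam, alpha = 1, backend = "cd")
    expect_lt(rlr_kkt_residual(m, X, y), 1e-6)
    expect_true(any(m$coefficients != 0) || lam > 0.05)
  }
})

test_that("the fit never does worse than the null model", {
  p <- random_problem(60, 10, delta = 1, seed = 47)
  for (lam in c(0.001, 0.1, 10)) {
    m <- fit_rlr(p$X, p$y, lam)
    null_obj <- rlr_objective_value(qlogis(mean(p$y)), rep(0, 10), p$X, p$y,
                                    lam, m$alpha)
    expect_lte(rlr_objective(m, p$X, p$y), null_obj + 1e-9)
  }
})

test_that("the L1 path is monotone in the penalty", {
  set.seed(48)
  n <- 60; d <- 15
  X <- matrix(rnorm(n * d), n)
  y <- rbinom(n, 1, plogis(X %*% c(2, -2, 1, rep(0, d - 3))))
  attr(X, "standardized") <- TRUE
  lams <- 10^seq(-3, 0.5, length.out = 20)
  l1 <- vapply(lams, function(l) {
    sum(abs(fit_rlr(X, y, l, alpha = 1, backend = "cd")$coefficients))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("prediction returns linear predictor, probability, and 0/1 labels", {
  p <- random_problem(50, 4, delta = 2, seed = 49)
  m <- fit_rlr(p$X, p$y, 0.01)
  pr <- predict(m, p$X)
  expect_equal(pr$probability, plogis(pr$decision))
  expect_true(all(pr$label %in% 0:1))
  expect_gt(mean(pr$label == p$y), 0.8)
  expect_error(predict(m, p$X[, 1:2]), "dimension")
  expect_error(fit_rlr(p$X, rep(1, 50), 0.1), "both classes")
})

test_that("single-column problems work through both backends", {
  set.seed(50)
  X <- matrix(rnorm(80), 80, 1)
  y <- rbinom(80, 1, plogis(2 * X[, 1]))
  attr(X, "standardized") <- TRUE
  m1 <- fit_rlr(X, y, 0.01, backend = "cd")
  m2 <- fit_rlr(X, y, 0.01, backend = "glmnet")
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-3)
})

test_that("coefficient maps export to NIfTI over the mask", {
  cohort <- tiny_cohort(n_per_class = 10, seed = 2)
  mask <- threshold_mask(cohort$template, 0.65)
  vec <- vectorize(cohort, mask)
  Xs <- apply_standardizer(fit_standardizer(vec$X), vec$X)
  m <- fit_rlr(Xs, vec$y, 0.05)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_coefficient_map(m, mask, f)
  vol <- read_nifti(f)$values
  expect_equal(sum(vol != 0), sum(m$coefficients != 0))
})
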