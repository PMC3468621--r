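# Soft/hard-margin linear SVM on precomputed kernels.

test_that("two-point problem recovers the closed-form solution", {
  # x1 = (1,0) y=+1, x2 = (-1,0) y=-1, C=10: w=(1,0), b=0, alpha=1/2
  X <- matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE)
  attr(X, "standardized") <- TRUE
  K <- linear_kernel(X)
  m <- fit_svm(K, c(1, 0), C = 10, X_train = X)
  expect_equal(m$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
  expect_equal(svm_weights(m), c(1, 0), tolerance = 1e-6)
  pred <- predict(m, X)
  expect_equal(pred$decision, c(1, -1), tolerance = 1e-6)
  expect_equal(pred$label, c(1L, 0L))
})

test_that("KKT conditions certify optimality on random problems", {
  worst <- 0
  for (s in 1:25) {
    set.seed(300 + s)
    n <- sample(10:40, 1); d <- sample(3:60, 1)
    p <- random_problem(n, d, delta = runif(1, 0, 1), seed = 300 + s)
    K <- linear_kernel(p$X)
    m <- fit_svm(K, p$y, C = 10^runif(1, -2, 2))
    worst <- max(worst, svm_kkt_residual(m, K))
    expect_true(all(m$alpha >= -1e-12 & m$alpha <= m$C + 1e-12))
    expect_lt(abs(sum(m$dual_coefficients)), 1e-8 * max(1, m$C))
  }
  expect_lt(worst, 1e-6)
})

test_that("kernel-path and primal-path predictions agree", {
  p <- random_problem(20, 40, delta = 0.8, seed = 7)
  K <- linear_kernel(p$X)
  m <- fit_svm(K, p$y, C = 1, X_train = p$X)
  Xnew <- matrix(rnorm(6 * 40), 6)
  attr(Xnew, "standardized") <- TRUE
  f_kernel <- predict(m, K_cross = Xnew %*% t(p$X))$decision
  f_primal <- drop(Xnew %*% svm_weights(m)) + m$b
  expect_lt(max(abs(f_kernel - f_primal)), 1e-8)
})

test_that("margin support vectors sit at |f| = 1 and ties go positive", {
  p <- random_problem(16, 50, delta = 1.5, seed = 12)  # separable-ish
  K <- linear_kernel(p$X)
  m <- fit_svm(K, p$y, C = hard_margin_C())
  f <- predict(m, K_cross = K$K)$decision
  free <- m$alpha > 1e-8 & m$alpha < m$C - 1e-8
  if (any(free)) {
    expect_lt(max(abs(abs(f[free]) - 1)), 1e-5)
  }
  expect_equal(predict(m, K_cross = matrix(0, 1, 16))$label,
               as.integer(m$b >= 0))
})

test_that("duplicating the dataset leaves the decision function unchanged", {
  # with the box constraint inactive (separable data, large C), duplication
  # does not change the margin problem, so the decision function is invariant
  p <- random_problem(14, 25, delta = 2, seed = 8)
  K1 <- linear_kernel(p$X)
  m1 <- fit_svm(K1, p$y, C = 1e4)
  expect_true(all(m1$alpha < 1e4 - 1e-6))
  X2 <- rbind(p$X, p$X)
  attr(X2, "standardized") <- TRUE
  m2 <- fit_svm(linear_kernel(X2), c(p$y, p$y), C = 1e4)
  Xnew <- matrix(rnorm(8 * 25), 8)
  f1 <- drop(Xnew %*% t(p$X) %*% m1$dual_coefficients) + m1$b
  f2 <- drop(Xnew %*% t(X2) %*% m2$dual_coefficients) + m2$b
  expect_lt(max(abs(f1 - f2)), 1e-4)
})

test_that("spectral (eigendecomposition) path reproduces kernel decisions", {
  p <- random_problem(18, 30, delta = 0.5, seed = 15)
  K <- linear_kernel(p$X)
  m <- fit_svm(K, p$y, C = 1)
  e <- eigen(K$K, symmetric = TRUE)
  K_spec <- e$vectors %*% (e$values * t(e$vectors))  # K = U S U'
  f_direct <- drop(K$K %*% m$dual_coefficients) + m$b
  f_spec <- drop(K_spec %*% m$dual_coefficients) + m$b
  expect_lt(max(abs(f_direct - f_spec)), 1e-8)
})

test_that("the penalty shrinks low-eigenvalue components more (generalized ridge)", {
  # diagonal kernel = orthogonal samples with eigenvalues s_i; the dual
  # optimum alpha_i = min(1/s_i, C) puts function-space components
  # f_i = alpha_i s_i = min(1, C s_i): small eigenvalues are shrunk harder
  # eigenvalues paired across classes so the equality constraint is
  # satisfied by the coordinate-wise optimum alpha_i = min(1/s_i, C)
  s <- c(4, 4, 0.25, 0.25)
  K <- diag(s)
  y <- c(1, 0, 1, 0)
  C <- 0.5
  stopifnot(sum(recode_pm1(y) * pmin(1 / s, C)) == 0)  # constraint inactive
  m <- fit_svm(K, y, C = C)
  f <- drop(diag(s) %*% m$dual_coefficients) + m$b
  target <- recode_pm1(y) * pmin(1, C * s)
  expect_equal(m$b, 0, tolerance = 1e-5)
  expect_equal(f, target, tolerance = 1e-4)
  shrinkage <- 1 - abs(f)
  expect_true(all(diff(shrinkage) >= -1e-6))  # smaller s_i -> more shrinkage
})

test_that("hard margin is the large-C limit", {
  p <- random_problem(12, 40, delta = 2, seed = 33)  # well separable
  K <- linear_kernel(p$X)
  mh <- fit_svm(K, p$y, C = hard_margin_C())
  expect_equal(mh$mode, "hard")
  ms <- fit_svm(K, p$y, C = 1e4)
  expect_lt(max(abs(mh$dual_coefficients - ms$dual_coefficients)), 1e-4)
})

test_that("inputs are validated", {
  p <- random_problem(10, 5, seed = 3)
  K <- linear_kernel(p$X)
  expect_error(fit_svm(K, p$y[1:5], C = 1), "label length")
  expect_error(fit_svm(K, rep(1, 10), C = 1), "both classes")
  expect_error(fit_svm(matrix(c(1, 2, 2, -5), 2), c(0, 1), C = 1),
               "positive semi-definite")
  m <- fit_svm(K, p$y, C = 1)
  expect_error(predict(m, K_cross = matrix(0, 2, 7)), "column count")
  expect_error(recode_pm1(c(0, 2)), "coded")
})
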