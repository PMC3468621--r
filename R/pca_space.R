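# Principal-component-space counterparts of the classifiers.
#
# PCA is fitted on the standardized training matrix (correlation scale).
# When d >> n the decomposition goes through the n x n Gram matrix rather
# than the d x d covariance, which is exact and far cheaper. Component
# selection for the incremental trace follows the reference protocol: the
# classifier is refitted on the first m components for m = 1..M and the
# maximum test accuracy over m is reported. That maximum is taken on the
# held-out test set, which is optimistic; a CV-based selector is available
# as a non-default alternative (`selector = "cv"`).

#' Fit PCA on a standardized training matrix
#'
#' Components of the training covariance, sorted by explained variance, with
#' a deterministic sign convention (the largest-magnitude loading of each
#' component is positive). At most `n - 1` components survive centering;
#' components with numerically zero variance are dropped.
#'
#' @param X standardized training matrix (n x d, n >= 2).
#' @return object of class `pca_projection`: `loadings` (d x m, orthonormal
#'   columns), `scores` (n x m training scores), `sdev` (component standard
#'   deviations), `explained_variance`, `center`.
#' @export
pca_fit <- function(X) {
  stopifnot(is.matrix(X))
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows for PCA")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (ncol(X) > n) {
    e <- eigen(tcrossprod(Xc), symmetric = TRUE)
    pos <- e$values > max(e$values, 0) * n * .Machine$double.eps
    m <- min(sum(pos), n - 1L)
    sv <- sqrt(e$values[seq_len(m)])
    U <- e$vectors[, seq_len(m), drop = FALSE]
    V <- crossprod(Xc, U) %*% diag(1 / sv, m)
    scores <- U %*% diag(sv, m)
  } else {
    s <- svd(Xc)
    pos <- s$d > max(s$d, 0) * n * .Machine$double.eps
    m <- min(sum(pos), n - 1L)
    sv <- s$d[seq_len(m)]
    V <- s$v[, seq_len(m), drop = FALSE]
    scores <- s$u[, seq_len(m), drop = FALSE] %*% diag(sv, m)
  }
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(m)) {
    piv <- which.max(abs(V[, j]))
    if (V[piv, j] < 0) {
      V[, j] <- -V[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(X)
  structure(list(loadings = V, scores = scores, sdev = sv / sqrt(n - 1),
                 explained_variance = sv^2 / (n - 1), center = ctr),
            class = "pca_projection")
}

#' Project new data into a fitted PCA space
#'
#' @param projection a `pca_projection`.
#' @param X_new matrix with the same columns (same standardizer as training).
#' @return score matrix (rows = subjects, columns = components).
#' @export
pca_transform <- function(projection, X_new) {
  stopifnot(inherits(projection, "pca_projection"), is.matrix(X_new))
  if (ncol(X_new) != length(projection$center)) {
    stop("feature dimension does not match the fitted projection")
  }
  S <- sweep(X_new, 2, projection$center) %*% projection$loadings
  rownames(S) <- rownames(X_new)
  S
}

# Incremental engines for the per-component traces. Kernels over the first m
# score columns grow by a rank-one update per component, and SVM solutions
# are warm-started across m (the box and equality constraints do not change),
# which keeps the m-loop tractable at full component counts.

trace_lrc <- function(S_tr, y_tr, S_te, y_te) {
  M <- ncol(S_tr)
  n <- nrow(S_tr)
  K <- matrix(0, n, n)
  Kx <- matrix(0, nrow(S_te), n)
  acc <- numeric(M)
  for (m in seq_len(M)) {
    K <- K + tcrossprod(S_tr[, m])
    Kx <- Kx + tcrossprod(S_te[, m], S_tr[, m])
    model <- fit_lrc(K, y_tr)
    pred <- predict(model, K_cross = Kx)
    acc[m] <- mean(pred$label == y_te)
  }
  list(accuracy = acc, cv_accuracy = rep(NA_real_, M))
}

trace_rlr <- function(S_tr, y_tr, S_te, y_te, grid, folds, alpha = 0.001) {
  M <- ncol(S_tr)
  k <- max(folds)
  lam <- sort(grid, decreasing = TRUE)
  L <- length(lam)
  acc <- numeric(M)
  cvacc <- numeric(M)
  # warm starts across m (per fold and per lambda); loose tolerances in the
  # fold fits: only the fold-accuracy ranking matters, and near-separable
  # small-lambda fits would otherwise grind at the iteration cap
  warm <- lapply(seq_len(k + 1L), function(f) {
    list(beta = matrix(0, 0, L), b0 = numeric(L))
  })
  for (m in seq_len(M)) {
    Sm <- S_tr[, seq_len(m), drop = FALSE]
    fold_acc <- matrix(NA_real_, L, k)
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- enet_logistic_path(Sm[tr, , drop = FALSE], as.numeric(y_tr[tr]),
                                lam, alpha, tol = 1e-4, max_outer = 5L,
                                max_inner = 10L,
                                beta_init = warm[[f]]$beta,
                                b0_init = warm[[f]]$b0)
      warm[[f]] <- list(beta = fit$beta, b0 = fit$b0)
      eta <- sweep(Sm[!tr, , drop = FALSE] %*% fit$beta, 2, fit$b0, "+")
      fold_acc[, f] <- colMeans((eta >= 0) == (y_tr[!tr] == 1))
    }
    mean_acc <- rowMeans(fold_acc)
    sel <- which(mean_acc >= max(mean_acc) - 1e-12)[1]  # lam sorted desc: first = most regularized
    refit <- enet_logistic_path(Sm, as.numeric(y_tr), lam, alpha,
                                tol = 1e-5, max_outer = 5L, max_inner = 10L,
                                beta_init = warm[[k + 1L]]$beta,
                                b0_init = warm[[k + 1L]]$b0)
    warm[[k + 1L]] <- list(beta = refit$beta, b0 = refit$b0)
    eta_te <- drop(refit$b0[sel] + S_te[, seq_len(m), drop = FALSE] %*% refit$beta[, sel])
    acc[m] <- mean(as.integer(eta_te >= 0) == y_te)
    cvacc[m] <- mean_acc[sel]
  }
  list(accuracy = acc, cv_accuracy = cvacc)
}

trace_svm <- function(S_tr, y_tr, S_te, y_te, grid, folds, eps = 1e-2,
                      max_iter = 5e3) {
  M <- ncol(S_tr)
  n <- nrow(S_tr)
  k <- max(folds)
  Cs <- sort(grid)
  nC <- length(Cs)
  acc <- numeric(M)
  cvacc <- numeric(M)
  # Incremental kernels per fold plus (alpha, gradient) warm states per
  # (fold, C). When the kernel grows by the rank-one update s s', the dual
  # gradient moves by y * s * sum(y * alpha * s) -- an O(n) correction that
  # avoids the O(n^2) gradient rebuild inside the solver.
  yy <- recode_pm1(y_tr)
  Kf <- lapply(seq_len(k), function(f) matrix(0, sum(folds != f), sum(folds != f)))
  Kc <- lapply(seq_len(k), function(f) matrix(0, sum(folds == f), sum(folds != f)))
  warm <- lapply(seq_len(k + 1L), function(f) vector("list", nC))
  Kfull <- matrix(0, n, n)
  Kte <- matrix(0, nrow(S_te), n)
  solve_warm <- function(K, yv, ci, slot, s_col) {
    st <- warm[[slot]][[ci]]
    a0 <- NULL
    g0 <- NULL
    if (!is.null(st)) {
      a0 <- st$alpha
      g0 <- st$gradient + yv * s_col * sum(yv * a0 * s_col)
    }
    sol <- smo_solve(K, yv, Cs[ci], eps, as.integer(max_iter), a0, g0)
    warm[[slot]][[ci]] <<- list(alpha = sol$alpha, gradient = sol$gradient)
    sol
  }
  for (m in seq_len(M)) {
    Kfull <- Kfull + tcrossprod(S_tr[, m])
    Kte <- Kte + tcrossprod(S_te[, m], S_tr[, m])
    fold_acc <- matrix(NA_real_, nC, k)
    for (f in seq_len(k)) {
      tr <- folds != f
      Kf[[f]] <- Kf[[f]] + tcrossprod(S_tr[tr, m])
      Kc[[f]] <- Kc[[f]] + tcrossprod(S_tr[!tr, m], S_tr[tr, m])
      for (ci in seq_len(nC)) {
        sol <- solve_warm(Kf[[f]], yy[tr], ci, f, S_tr[tr, m])
        pred <- as.integer(drop(Kc[[f]] %*% sol$coef) + sol$b >= 0)
        fold_acc[ci, f] <- mean(pred == y_tr[!tr])
      }
    }
    mean_acc <- rowMeans(fold_acc)
    sel <- which(mean_acc >= max(mean_acc) - 1e-12)[1]  # Cs ascending: first = most regularized
    sol <- solve_warm(Kfull, yy, sel, k + 1L, S_tr[, m])
    pred <- as.integer(drop(Kte %*% sol$coef) + sol$b >= 0)
    acc[m] <- mean(pred == y_te)
    cvacc[m] <- mean_acc[sel]
  }
  list(accuracy = acc, cv_accuracy = cvacc)
}

#' Incremental component-count accuracy trace
#'
#' For m = 1..M (components ordered by explained variance), fit the method on
#' the first m score columns — with its cross-validated hyperparameter search
#' for `"rlr"`/`"svm"` — and record test accuracy. The default selector takes
#' the maximum over the trace on the test scores (the reference protocol,
#' optimistic by construction); `selector = "cv"` instead picks m by the CV
#' accuracy of the refitted model and reports the test accuracy at that m.
#'
#' @param scores_train,y_train training scores and labels.
#' @param scores_test,y_test test scores and labels.
#' @param method `"lrc"`, `"rlr"` or `"svm"`.
#' @param grid hyperparameter grid for rlr/svm (default [default_grids()]).
#' @param cv_seed seed for fold assignment.
#' @param selector `"test_max"` (reference behavior) or `"cv"`.
#' @param ... passed to the fitting routines.
#' @return object of class `component_trace`: `accuracy` (length M),
#'   `best_count`, `best_accuracy`, `selector`.
#' @export
incremental_component_accuracy <- function(scores_train, y_train, scores_test,
                                           y_test, method = c("lrc", "rlr", "svm"),
                                           grid = NULL, cv_seed = 1L,
                                           selector = c("test_max", "cv"), ...) {
  method <- match.arg(method)
  selector <- match.arg(selector)
  stopifnot(is.matrix(scores_train), is.matrix(scores_test),
            ncol(scores_train) == ncol(scores_test), ncol(scores_train) >= 1)
  y_train <- as.integer(y_train)
  y_test <- as.integer(y_test)
  if (method == "lrc") {
    res <- trace_lrc(scores_train, y_train, scores_test, y_test)
  } else {
    if (is.null(grid)) {
      grid <- if (method == "rlr") default_grids()$lambda else default_grids()$C
    }
    folds <- stratified_folds(y_train, k = 10, seed = cv_seed)
    res <- if (method == "rlr") {
      trace_rlr(scores_train, y_train, scores_test, y_test, grid, folds, ...)
    } else {
      trace_svm(scores_train, y_train, scores_test, y_test, grid, folds, ...)
    }
  }
  acc <- res$accuracy
  cvacc <- res$cv_accuracy
  best <- if (selector == "test_max" || method == "lrc") {
    which.max(acc)
  } else {
    which.max(cvacc)
  }
  structure(list(accuracy = acc, cv_accuracy = cvacc,
                 best_count = best, best_accuracy = acc[best],
                 method = method, selector = selector),
            class = "component_trace")
}

#' @export
print.component_trace <- function(x, ...) {
  cat(sprintf("<component_trace %s: best %.3f at m=%d of %d (%s selector)>\n",
              x$method, x$best_accuracy, x$best_count, length(x$accuracy),
              x$selector))
  invisible(x)
}
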