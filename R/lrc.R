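# Dual-form linear regression classifier (LRC).
#
# Least squares on 0/1 labels, solved in the space spanned by the kernel:
# a = K^+ y with K = X X' and the Moore-Penrose pseudo-inverse, so the primal
# weights w = X'a are the minimum-norm least-squares solution X^+ y. The
# pseudo-inverse filters out only zero singular values (below a numerical
# cutoff); unlike the regularized classifiers, nothing dampens small nonzero
# singular values, which is exactly why this classifier is sensitive to kernel
# conditioning.
#
# By default the fit carries an intercept, handled by standard kernel
# centering: a = (HKH)^+ (y - ybar) with H = I - 11'/n, and
# f(x) = ybar + (k_x - K1/n)' a. For balanced standardized data the label
# mean cannot transfer to held-out subjects through an intercept-free
# minimum-norm interpolator (held-out decisions center near 0, not 0.5), so
# the intercept is what makes the 0.5 threshold meaningful off the training
# set. `intercept = FALSE` recovers the literal pseudo-inverse solution
# a = K^+ y, whose dual-primal algebra X'(XX')^+ y = X^+ y is tested
# explicitly.

#' Fit the dual-form least-squares classifier
#'
#' Computes dual coefficients via the symmetric eigendecomposition of the
#' (optionally centered) kernel, treating eigenvalues below
#' `n * eps * lambda_max` as zero — the same cutoff convention as the
#' conditioning diagnostics. No hyperparameter is tuned.
#'
#' @param K a `linear_kernel` (from the training features) or plain matrix.
#' @param y integer labels in \{0, 1\} aligned with K's rows.
#' @param X_train optional training feature matrix; stored to enable
#'   prediction from raw feature vectors. If omitted, predictions require a
#'   precomputed cross-kernel.
#' @param intercept fit the label mean via kernel centering (default TRUE);
#'   `FALSE` gives the plain minimum-norm solution `a = K^+ y`.
#' @param svd_cutoff relative eigenvalue cutoff; default `n * eps`.
#' @return object of class `lrc_model`: `dual_coefficients`, `offset` (the
#'   scalar added to the kernel decision value; 0 without intercept),
#'   `threshold` (0.5), `X_train`, `n`, `rank_used`.
#' @export
fit_lrc <- function(K, y, X_train = NULL, intercept = TRUE,
                    svd_cutoff = NULL) {
  Km <- as_kernel_matrix(K)
  y <- as.numeric(y)
  if (length(y) != nrow(Km)) stop("label length does not match kernel size")
  n <- nrow(Km)
  if (intercept) {
    ybar <- mean(y)
    rm_ <- rowMeans(Km)
    Kc <- Km - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(Km)
    target <- y - ybar
  } else {
    Kc <- Km
    target <- y
  }
  e <- eigen(Kc, symmetric = TRUE)
  if (is.null(svd_cutoff)) svd_cutoff <- n * .Machine$double.eps
  lam <- e$values
  keep <- lam > svd_cutoff * max(lam, 0)
  inv <- numeric(n)
  inv[keep] <- 1 / lam[keep]
  a <- drop(e$vectors %*% (inv * crossprod(e$vectors, target)))
  offset <- if (intercept) mean(y) - sum(rowMeans(Km) * a) else 0
  structure(list(dual_coefficients = a, offset = offset, threshold = 0.5,
                 intercept = intercept, X_train = X_train, n = n,
                 rank_used = sum(keep)),
            class = "lrc_model")
}

#' Primal weights of a fitted LRC
#' @param model an `lrc_model` fitted with `X_train` stored.
#' @return numeric length-d weight vector `w = X' a`.
#' @export
lrc_weights <- function(model) {
  stopifnot(inherits(model, "lrc_model"))
  if (is.null(model$X_train)) stop("model was fitted without X_train")
  drop(crossprod(model$X_train, model$dual_coefficients))
}

#' Predict with the dual-form least-squares classifier
#'
#' Decision value `f(x) = <x, w> + offset` with `w = X'a` (equivalently
#' `<K(x, .), a> + offset`); label 1 when `f(x) >= 0.5` (ties go to class 1).
#'
#' @param object an `lrc_model`.
#' @param X_new new feature matrix (same columns as training), or `NULL` if
#'   `K_cross` is given.
#' @param K_cross optional precomputed cross-kernel (rows = new subjects,
#'   columns = training subjects).
#' @param ... unused.
#' @return list with `decision` (numeric) and `label` (integer 0/1).
#' @export
predict.lrc_model <- function(object, X_new = NULL, K_cross = NULL, ...) {
  if (is.null(K_cross)) {
    if (is.null(X_new) || is.null(object$X_train)) {
      stop("need X_new (with stored X_train) or K_cross")
    }
    if (ncol(X_new) != ncol(object$X_train)) {
      stop("feature dimension does not match training data")
    }
    if (!is_standardized(X_new) &&
        !is.null(object$X_train) && is_standardized(object$X_train)) {
      warning("predicting on unstandardized input with a model trained on standardized features")
    }
    f <- drop(X_new %*% crossprod(object$X_train, object$dual_coefficients))
  } else {
    K_cross <- as_kernel_matrix(K_cross)
    if (ncol(K_cross) != object$n) stop("K_cross column count must equal training n")
    f <- drop(K_cross %*% object$dual_coefficients)
  }
  f <- f + object$offset
  list(decision = f, label = as.integer(f >= object$threshold))
}
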