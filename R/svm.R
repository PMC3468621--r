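# Soft/hard-margin linear SVM on a precomputed linear kernel.
#
# The dual problem is solved by an SMO routine (src/smo.cpp). In the spectral
# view K = U S U', the penalty acts as a generalized ridge: solution
# components along eigenvectors with smaller eigenvalues are penalized more
# strongly, which is what makes the soft-margin machine robust to
# ill-conditioned kernels. Hard margin is soft margin with C = 1e6.

#' Cost value used for the hard-margin SVM
#' @return 1e6.
#' @export
hard_margin_C <- function() 1e6

#' Fit a linear SVM from a precomputed kernel
#'
#' Solves the soft-margin dual with box constraint `C`. Labels may be given
#' as \{0, 1\} (0 = CN, 1 = AD) or \{-1, +1\}; they are recoded internally to
#' -1/+1 with class 1 (AD) positive.
#'
#' @param K a `linear_kernel` (or plain PSD matrix) of the training features.
#' @param y labels.
#' @param C positive cost; `hard_margin_C()` for the hard-margin limit.
#' @param eps KKT stopping tolerance (maximal violating-pair gap).
#' @param max_iter iteration cap for the SMO loop.
#' @param X_train optional feature matrix, stored for primal-path prediction.
#' @param psd_tol tolerance for the PSD check: smallest eigenvalue must be
#'   >= -psd_tol * largest.
#' @param check_psd set `FALSE` to skip the PSD eigen-check (used by inner CV
#'   loops where the same kernel is refitted many times).
#' @param warm_alpha optional warm-start alpha vector from a previous fit at
#'   a smaller C (ignored if infeasible).
#' @return object of class `svm_model`: `dual_coefficients` (signed,
#'   `y_i alpha_i`), `alpha`, `b`, `C`, `mode`, `converged`, `iterations`,
#'   `gap`, `X_train`, `n`.
#' @export
fit_svm <- function(K, y, C, eps = 1e-6, max_iter = 2e6, X_train = NULL,
                    psd_tol = 1e-8, check_psd = TRUE, warm_alpha = NULL) {
  Km <- as_kernel_matrix(K)
  stopifnot(is.matrix(Km), nrow(Km) == ncol(Km), C > 0)
  yy <- recode_pm1(y)
  if (length(yy) != nrow(Km)) stop("label length does not match kernel size")
  if (length(unique(yy)) < 2L) stop("both classes must be present to fit SVM")
  if (check_psd) {
    ev <- eigen(Km, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -psd_tol * max(abs(ev))) {
      stop(sprintf("kernel is not positive semi-definite (min eig %.3g)", min(ev)))
    }
  }
  sol <- smo_solve(Km, yy, C, eps, as.integer(max_iter), warm_alpha)
  if (!sol$converged) {
    warning(sprintf("SMO hit the iteration cap (%d) with gap %.3g", max_iter,
                    sol$gap))
  }
  structure(list(dual_coefficients = sol$coef, alpha = sol$alpha, b = sol$b,
                 C = C, mode = if (C >= hard_margin_C()) "hard" else "soft",
                 converged = sol$converged, iterations = sol$iterations,
                 gap = sol$gap, y = yy, X_train = X_train, n = nrow(Km)),
            class = "svm_model")
}

#' Predict with a fitted kernel SVM
#'
#' `f(x) = sum_i coef_i K(x, x_i) + b`; label +1 (class AD, coded 1) when
#' `f >= 0` (ties to the positive class), reported on the 0/1 scale.
#'
#' @param object an `svm_model`.
#' @param X_new new feature matrix (requires `X_train` stored at fit time),
#'   or `NULL` if `K_cross` is supplied.
#' @param K_cross precomputed cross-kernel (rows = new subjects, columns =
#'   training subjects).
#' @param ... unused.
#' @return list with `decision` and `label` (integer 0/1).
#' @export
predict.svm_model <- function(object, X_new = NULL, K_cross = NULL, ...) {
  if (is.null(K_cross)) {
    if (is.null(X_new) || is.null(object$X_train)) {
      stop("need X_new (with stored X_train) or K_cross")
    }
    if (ncol(X_new) != ncol(object$X_train)) {
      stop("feature dimension does not match training data")
    }
    K_cross <- X_new %*% t(object$X_train)
  } else {
    K_cross <- as_kernel_matrix(K_cross)
    if (ncol(K_cross) != object$n) {
      stop("K_cross column count must equal training n")
    }
  }
  f <- drop(K_cross %*% object$dual_coefficients) + object$b
  list(decision = f, label = as.integer(f >= 0))
}

#' Primal weight vector of a linear-kernel SVM
#' @param model an `svm_model` fitted with `X_train` stored.
#' @return numeric weight vector `w = X' (y * alpha)`.
#' @export
svm_weights <- function(model) {
  stopifnot(inherits(model, "svm_model"))
  if (is.null(model$X_train)) stop("model was fitted without X_train")
  drop(crossprod(model$X_train, model$dual_coefficients))
}

#' KKT residual of a fitted SVM
#'
#' Checks the complete optimality conditions of the convex dual: for each
#' training point, `alpha = 0` requires `y f >= 1`, `alpha = C` requires
#' `y f <= 1`, and free vectors require `y f = 1`. Returns the largest
#' violation in margin units.
#'
#' @param model an `svm_model`.
#' @param K the training kernel it was fitted on.
#' @return scalar maximum KKT violation.
#' @export
svm_kkt_residual <- function(model, K) {
  Km <- as_kernel_matrix(K)
  f <- drop(Km %*% model$dual_coefficients) + model$b
  yf <- model$y * f
  a <- model$alpha
  C <- model$C
  free_tol <- 1e-9 * max(C, 1)
  viol <- 0
  at0 <- a <= free_tol
  atC <- a >= C - free_tol
  free <- !at0 & !atC
  if (any(at0)) viol <- max(viol, max(pmax(1 - yf[at0], 0)))
  if (any(atC)) viol <- max(viol, max(pmax(yf[atC] - 1, 0)))
  if (any(free)) viol <- max(viol, max(abs(yf[free] - 1)))
  viol
}

#' Recode labels to -1/+1
#'
#' Accepts \{0, 1\} (0 = CN, 1 = AD) or \{-1, +1\}; class 1 / +1 is positive.
#' Centralized so the label convention is converted (and tested) in one place.
#'
#' @param y numeric or integer labels.
#' @return integer vector of -1/+1.
#' @export
recode_pm1 <- function(y) {
  y <- as.integer(y)
  if (all(y %in% c(0L, 1L))) {
    ifelse(y == 1L, 1L, -1L)
  } else if (all(y %in% c(-1L, 1L))) {
    y
  } else {
    stop("labels must be coded {0,1} or {-1,+1}")
  }
}
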