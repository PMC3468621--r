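# Elastic-net regularized logistic regression (RLR).
#
# Objective (for labels y in {0,1}, features x_i, linear predictor
# eta_i = b0 + x_i' beta):
#
#   (1/n) sum_i [ log(1 + exp(eta_i)) - y_i eta_i ]
#     + lambda * [ (1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1 ]
#
# minimized by cyclic coordinate descent on the penalized quadratic
# approximation, as implemented in glmnet — the library whose optimization
# problem this module's contract is defined by. The package keeps its own
# model surface, objective function and KKT checks so the fit can be verified
# against an independent generic optimizer.

#' Fit elastic-net regularized logistic regression at one penalty value
#'
#' @param X standardized feature matrix (n x d).
#' @param y integer labels in \{0, 1\}; both classes must be present.
#' @param lambda nonnegative penalty strength.
#' @param alpha elastic-net mixing weight in `[0, 1]` (1 = lasso, 0 = ridge).
#'   Default 0.001: a nearly quadratic penalty whose small L1 component still
#'   confers sparsity at strong penalties.
#' @param thresh coordinate-descent convergence threshold (passed to the
#'   backend); the default is tight enough that stationarity (KKT) residuals
#'   fall below 1e-6 on problems of the scale used here.
#' @param maxit maximum number of coordinate-descent passes.
#' @param backend `"auto"` (the in-package coordinate-descent solver for
#'   small dense problems, glmnet above 600 features), `"cd"` or `"glmnet"`.
#'   Both minimize the identical objective; fits agree to solver tolerance.
#' @return object of class `rlr_model`: `intercept`, `coefficients`,
#'   `lambda`, `alpha`, `converged`, `npasses`.
#' @export
fit_rlr <- function(X, y, lambda, alpha = 0.001, thresh = 1e-10,
                    maxit = 1e6, backend = c("auto", "cd", "glmnet")) {
  stopifnot(is.matrix(X), lambda >= 0, alpha >= 0, alpha <= 1)
  backend <- match.arg(backend)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present to fit RLR")
  if (length(y) != nrow(X)) stop("label length does not match feature rows")
  d <- ncol(X)
  if (backend == "auto") backend <- if (d <= 600L) "cd" else "glmnet"
  # A single interior lambda can be fragile for coordinate-descent warm
  # starts; fit a short decreasing path ending at the requested value.
  lam_path <- if (lambda > 0) lambda * c(8, 4, 2, 1) else c(0.1, 0.01, 0)
  k <- length(lam_path)
  if (backend == "cd") {
    fit <- enet_logistic_path(X, as.numeric(y), lam_path, alpha,
                              tol = 1e-9, max_outer = 100L,
                              max_inner = as.integer(min(maxit, 500)))
    beta <- fit$beta[, k]
    b0 <- fit$b0[k]
    converged <- fit$converged[k]
    npasses <- sum(fit$outer_iterations)
  } else {
    Xfit <- if (d == 1L) cbind(X, 0) else X  # glmnet needs >= 2 columns
    fit <- glmnet::glmnet(Xfit, factor(y, levels = c(0, 1)),
                          family = "binomial", alpha = alpha,
                          lambda = lam_path, standardize = FALSE,
                          thresh = thresh, maxit = maxit)
    beta <- as.numeric(fit$beta[, k])[seq_len(d)]
    b0 <- as.numeric(fit$a0[k])
    npasses <- fit$npasses
    converged <- npasses < maxit
  }
  if (!converged) {
    stop(sprintf(
      "RLR did not converge (objective %.6g)",
      rlr_objective_value(b0, beta, X, y, lambda, alpha)))
  }
  structure(list(intercept = b0, coefficients = beta, lambda = lambda,
                 alpha = alpha, converged = converged, npasses = npasses,
                 backend = backend),
            class = "rlr_model")
}

#' Penalized-deviance objective of the RLR problem
#'
#' Mean binomial negative log-likelihood plus the elastic-net penalty;
#' exposed so fits can be audited against independent optimizers.
#'
#' @param b0 intercept.
#' @param beta coefficient vector.
#' @param X,y data.
#' @param lambda,alpha penalty parameters.
#' @return scalar objective value.
#' @export
rlr_objective_value <- function(b0, beta, X, y, lambda, alpha) {
  eta <- drop(b0 + X %*% beta)
  # numerically stable log(1 + exp(eta))
  loglik <- sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) / length(y)
  pen <- lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
  loglik + pen
}

#' @rdname rlr_objective_value
#' @param model an `rlr_model`.
#' @export
rlr_objective <- function(model, X, y) {
  stopifnot(inherits(model, "rlr_model"))
  rlr_objective_value(model$intercept, model$coefficients, X, y,
                      model$lambda, model$alpha)
}

#' KKT (stationarity) residual of an RLR fit
#'
#' For the convex elastic-net problem the subgradient conditions are a
#' complete optimality certificate: for active coordinates the penalized
#' gradient must vanish; for inactive ones it must lie within the L1
#' threshold. Returns the largest violation.
#'
#' @param model an `rlr_model`.
#' @param X,y the training data the model was fitted on.
#' @return scalar maximum KKT violation.
#' @export
rlr_kkt_residual <- function(model, X, y) {
  stopifnot(inherits(model, "rlr_model"))
  p <- predict(model, X)$probability
  r <- (p - y) / length(y)
  g <- drop(crossprod(X, r)) + model$lambda * (1 - model$alpha) * model$coefficients
  l1 <- model$lambda * model$alpha
  active <- model$coefficients != 0
  viol <- abs(sum(r))  # intercept stationarity
  if (any(active)) {
    viol <- max(viol, abs(g[active] + l1 * sign(model$coefficients[active])))
  }
  if (any(!active)) {
    viol <- max(viol, max(pmax(abs(g[!active]) - l1, 0)))
  }
  viol
}

#' Predict with a fitted RLR model
#'
#' @param object an `rlr_model`.
#' @param X_new feature matrix with matching columns.
#' @param ... unused.
#' @return list with `decision` (linear predictor), `probability`, and
#'   `label` (1 when probability >= 0.5; ties to class 1).
#' @export
predict.rlr_model <- function(object, X_new, ...) {
  stopifnot(is.matrix(X_new))
  if (ncol(X_new) != length(object$coefficients)) {
    stop("feature dimension does not match training data")
  }
  eta <- drop(object$intercept + X_new %*% object$coefficients)
  p <- 1 / (1 + exp(-eta))
  list(decision = eta, probability = p, label = as.integer(eta >= 0))
}

#' Export an RLR coefficient map to NIfTI over a mask
#'
#' Writes the fitted voxel coefficients back into brain space for visual
#' inspection (zero outside the mask).
#'
#' @param model an `rlr_model` fitted on features from `mask`.
#' @param mask the `binary_mask` defining the columns.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_coefficient_map <- function(model, mask, path) {
  stopifnot(inherits(model, "rlr_model"), inherits(mask, "binary_mask"))
  if (length(model$coefficients) != mask_size(mask)) {
    stop("coefficient length does not match mask size")
  }
  vol <- array(0, mask$grid$dims)
  vol[mask$linear_index] <- model$coefficients
  write_nifti(vol, path, mask$grid$voxel_size_mm)
  invisible(path)
}
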