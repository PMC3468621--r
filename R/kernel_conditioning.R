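# Linear kernel (Gram) matrices and SVD-based conditioning diagnostics.
#
# For a feature matrix X (n subjects x d voxels) the linear kernel is
# K = X X'. Its singular-value structure measures how ill-posed the
# classification problem is: the condition number is sigma_max / sigma_min,
# infinite for a singular kernel. Note cond(K) = cond(X)^2 in exact
# arithmetic; diagnostics here are reported on the kernel scale, as is
# conventional for kernel machines.

#' Build the linear kernel matrix K = X X'
#'
#' Exact symmetry is enforced by averaging with the transpose (guards against
#' floating-point asymmetry from blocked BLAS).
#'
#' @param X numeric feature matrix (n x d), typically standardized; a warning
#'   is emitted otherwise.
#' @return object of class `linear_kernel`: list with `K` (n x n), `n`, `d`.
#' @export
linear_kernel <- function(X) {
  stopifnot(is.matrix(X))
  if (any(!is.finite(X))) stop("feature matrix contains non-finite entries")
  if (!is_standardized(X)) {
    warning("building a kernel from unstandardized features")
  }
  K <- tcrossprod(X)
  K <- (K + t(K)) / 2
  structure(list(K = K, n = nrow(X), d = ncol(X)), class = "linear_kernel")
}

#' @export
print.linear_kernel <- function(x, ...) {
  cat(sprintf("<linear_kernel %d x %d (from %d features)>\n", x$n, x$n, x$d))
  invisible(x)
}

as_kernel_matrix <- function(K) {
  if (inherits(K, "linear_kernel")) K$K else K
}

#' SVD conditioning report for a kernel matrix
#'
#' Singular values (descending), numerical rank, condition number
#' sigma_max / sigma_min (`Inf` when sigma_min = 0) and its reciprocal. The
#' default rank tolerance is the standard numerical-rank convention
#' `n * .Machine$double.eps * sigma_max`.
#'
#' @param K a `linear_kernel` or plain symmetric matrix.
#' @param rank_tol absolute tolerance on singular values for the rank count;
#'   `NULL` (default) uses `n * eps * sigma_max`.
#' @return object of class `conditioning_report`: `singular_values`, `rank`,
#'   `condition_number`, `reciprocal_condition`, `n`, `d`, `rank_tol`.
#' @export
svd_conditioning <- function(K, rank_tol = NULL) {
  d_src <- if (inherits(K, "linear_kernel")) K$d else NA_integer_
  Km <- as_kernel_matrix(K)
  stopifnot(is.matrix(Km), nrow(Km) == ncol(Km))
  sv <- sort(svd(Km, nu = 0, nv = 0)$d, decreasing = TRUE)
  smax <- sv[1]
  if (is.null(rank_tol)) rank_tol <- nrow(Km) * .Machine$double.eps * smax
  rank <- sum(sv > rank_tol)
  if (smax == 0) {
    warning("all-zero kernel: rank 0, condition number undefined")
    cond <- NaN
  } else {
    smin <- sv[length(sv)]
    cond <- if (smin == 0) Inf else smax / smin
  }
  structure(list(singular_values = sv, rank = rank,
                 condition_number = cond,
                 reciprocal_condition = if (is.nan(cond)) NaN else 1 / cond,
                 n = nrow(Km), d = d_src, rank_tol = rank_tol),
            class = "conditioning_report")
}

#' @export
print.conditioning_report <- function(x, ...) {
  cat(sprintf("<conditioning_report n=%d rank=%d cond=%.4g rcond=%.4g>\n",
              x$n, x$rank, x$condition_number, x$reciprocal_condition))
  invisible(x)
}

#' Aggregate conditioning reports across iterations
#'
#' Element-wise median of the singular-value spectra (the spectrum summary of
#' repeated draws), plus median and IQR of the condition numbers.
#'
#' @param reports list of `conditioning_report`s with identical `n`.
#' @return object of class `spectrum_summary`: `median_singular_values`,
#'   `n_iterations`, `condition_median`, `condition_iqr`, `ranks`.
#' @export
aggregate_spectra <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "conditioning_report")))
  ns <- vapply(reports, function(r) r$n, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("reports mix kernel sizes: ", paste(unique(ns), collapse = ", "))
  }
  S <- vapply(reports, function(r) r$singular_values, numeric(ns[1]))
  conds <- vapply(reports, function(r) r$condition_number, numeric(1))
  structure(list(
    median_singular_values = apply(matrix(S, nrow = ns[1]), 1, stats::median),
    n_iterations = length(reports),
    condition_median = stats::median(conds),
    condition_iqr = stats::IQR(conds),
    ranks = vapply(reports, function(r) r$rank, integer(1))
  ), class = "spectrum_summary")
}

#' Serialize a conditioning report to JSON
#' @param report a `conditioning_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conditioning_report <- function(report, path) {
  stopifnot(inherits(report, "conditioning_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Export spectra to long-format CSV (iteration, index, sigma)
#' @param reports list of `conditioning_report`s.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(reports, path) {
  rows <- do.call(rbind, lapply(seq_along(reports), function(i) {
    sv <- reports[[i]]$singular_values
    data.frame(iteration = i, index = seq_along(sv), sigma = sv)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
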