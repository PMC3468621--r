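# From volumes to feature matrices: threshold the probability template, mask,
# vectorize, and standardize voxel-wise.

#' Threshold a probability template into a binary analysis mask
#'
#' Voxels strictly above `t` are included. The voxel ordering is fixed and
#' lexicographic with the first coordinate fastest (R's native array order),
#' and is never permuted between training and test data.
#'
#' @param template a `probability_template`.
#' @param t threshold in `[0, 1]`.
#' @return an object of class `binary_mask` with `grid`, `flags` (logical
#'   3-D array), `voxel_index_map` (integer matrix of included coordinates,
#'   1-based) and `threshold`.
#' @export
threshold_mask <- function(template, t) {
  stopifnot(inherits(template, "probability_template"),
            is.numeric(t), length(t) == 1L, t >= 0, t <= 1)
  flags <- template$values > t
  idx <- which(flags)
  if (length(idx) == 0L) {
    stop(sprintf("threshold %g produces an empty mask", t))
  }
  coords <- arrayInd(idx, template$grid$dims)
  structure(list(grid = template$grid, flags = flags,
                 voxel_index_map = coords, linear_index = idx, threshold = t),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d voxels at threshold %g on %d x %d x %d grid>\n",
              length(x$linear_index), x$threshold,
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask a `binary_mask`.
#' @return integer.
#' @export
mask_size <- function(mask) length(mask$linear_index)

#' Vectorize a cohort under a mask
#'
#' Row i of the feature matrix holds subject i's masked voxels in
#' `voxel_index_map` order.
#'
#' @param cohort a `gm_cohort` (or plain list of [gm_volume()]s).
#' @param mask a `binary_mask` on the same grid.
#' @return list with `X` (n x d feature matrix, attribute `standardized` set
#'   to `FALSE`, rownames = subject ids), `y` (integer labels, 0 = CN,
#'   1 = AD), `mask`.
#' @export
vectorize <- function(cohort, mask) {
  stopifnot(inherits(mask, "binary_mask"))
  vols <- if (inherits(cohort, "gm_cohort")) cohort$volumes else cohort
  labels <- if (inherits(cohort, "gm_cohort")) {
    cohort$labels
  } else {
    as.integer(vapply(vols, function(v) v$label == "AD", logical(1)))
  }
  n <- length(vols)
  X <- matrix(0, n, mask_size(mask))
  ids <- character(n)
  for (i in seq_len(n)) {
    v <- vols[[i]]
    if (!same_grid(v$grid, mask$grid)) {
      stop("volume grid does not match mask grid for subject ", v$subject_id)
    }
    X[i, ] <- v$values[mask$linear_index]
    ids[i] <- v$subject_id
  }
  rownames(X) <- ids
  attr(X, "standardized") <- FALSE
  list(X = X, y = labels, mask = mask)
}

#' Fit voxel-wise standardization parameters on training data
#'
#' Per-column mean and sample standard deviation (denominator n - 1). Columns
#' with zero standard deviation are flagged and standardized to zero instead
#' of being dropped, so dimensions stay comparable across iterations.
#'
#' @param X_train numeric matrix (n >= 2 rows).
#' @return an object of class `standardizer` with `mean`, `sd`, `zero_sd`
#'   (logical flags).
#' @export
fit_standardizer <- function(X_train) {
  stopifnot(is.matrix(X_train))
  if (nrow(X_train) < 2L) stop("need at least 2 training rows to standardize")
  mu <- colMeans(X_train)
  sdv <- sqrt(colSums(sweep(X_train, 2, mu)^2) / (nrow(X_train) - 1))
  zero <- sdv == 0
  structure(list(mean = mu, sd = sdv, zero_sd = zero), class = "standardizer")
}

#' Apply (or invert) standardization
#'
#' @param params a `standardizer`.
#' @param X numeric matrix with matching column count.
#' @return standardized matrix (attribute `standardized = TRUE`); zero-sd
#'   columns map to 0.
#' @export
apply_standardizer <- function(params, X) {
  stopifnot(inherits(params, "standardizer"), is.matrix(X))
  if (ncol(X) != length(params$mean)) {
    stop(sprintf("dimension mismatch: %d columns vs %d fitted parameters",
                 ncol(X), length(params$mean)))
  }
  sd_safe <- ifelse(params$zero_sd, 1, params$sd)
  Xs <- sweep(sweep(X, 2, params$mean), 2, sd_safe, "/")
  if (any(params$zero_sd)) Xs[, params$zero_sd] <- 0
  attr(Xs, "standardized") <- TRUE
  Xs
}

#' @rdname apply_standardizer
#' @export
invert_standardizer <- function(params, X) {
  stopifnot(inherits(params, "standardizer"), is.matrix(X))
  if (ncol(X) != length(params$mean)) stop("dimension mismatch")
  sd_safe <- ifelse(params$zero_sd, 1, params$sd)
  Xr <- sweep(sweep(X, 2, sd_safe, "*"), 2, params$mean, "+")
  attr(Xr, "standardized") <- FALSE
  Xr
}

is_standardized <- function(X) isTRUE(attr(X, "standardized"))
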