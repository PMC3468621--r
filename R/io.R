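# Serialization helpers: masks and component maps to NIfTI, feature matrices
# to compressed column-major binary with a coordinate sidecar, models and
# split plans to JSON, CV traces and component traces to CSV.

#' Write a binary mask as a NIfTI volume
#'
#' Included voxels are 1, excluded 0 (uint8).
#'
#' @param mask a `binary_mask`.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  vol <- array(0, mask$grid$dims)
  vol[mask$linear_index] <- 1
  write_nifti(vol, path, mask$grid$voxel_size_mm, datatype = "uint8")
  invisible(path)
}

#' Write PCA loadings as NIfTI component maps over a mask
#'
#' One volume per requested component, zero outside the mask.
#'
#' @param projection a `pca_projection` fitted on features from `mask`.
#' @param mask the `binary_mask` defining the feature columns.
#' @param dir output directory.
#' @param components integer vector of component indices (default first 3).
#' @return the written paths, invisibly.
#' @export
write_component_maps <- function(projection, mask, dir,
                                 components = seq_len(min(3L, ncol(projection$loadings)))) {
  stopifnot(inherits(projection, "pca_projection"), inherits(mask, "binary_mask"))
  if (nrow(projection$loadings) != mask_size(mask)) {
    stop("loadings do not match the mask size")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(components, function(k) {
    vol <- array(0, mask$grid$dims)
    vol[mask$linear_index] <- projection$loadings[, k]
    p <- file.path(dir, sprintf("component_%03d.nii.gz", k))
    write_nifti(vol, p, mask$grid$voxel_size_mm)
    p
  }, character(1))
  invisible(paths)
}

#' Write / read a feature matrix as compressed column-major binary
#'
#' Writes `<prefix>.bin.gz` (doubles, column-major), `<prefix>_voxels.csv`
#' (the mask's voxel coordinates, one row per column of X) and
#' `<prefix>_meta.json` (dimensions, subject ids, standardization flag).
#'
#' @param X feature matrix (n x d), rownames = subject ids.
#' @param mask the `binary_mask` its columns come from (or `NULL`).
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_feature_matrix <- function(X, mask, prefix) {
  stopifnot(is.matrix(X))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "binary_mask"), ncol(X) == mask_size(mask))
    coords <- as.data.frame(mask$voxel_index_map)
    names(coords) <- c("x", "y", "z")
    utils::write.csv(coords, paste0(prefix, "_voxels.csv"), row.names = FALSE)
  }
  con <- gzfile(paste0(prefix, ".bin.gz"), "wb")
  writeBin(as.numeric(X), con, size = 8)
  close(con)
  jsonlite::write_json(
    list(n = nrow(X), d = ncol(X),
         subject_ids = rownames(X),
         standardized = isTRUE(attr(X, "standardized"))),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  con <- gzfile(paste0(prefix, ".bin.gz"), "rb")
  vals <- readBin(con, "double", n = meta$n * meta$d, size = 8)
  close(con)
  X <- matrix(vals, meta$n, meta$d)
  rownames(X) <- meta$subject_ids
  attr(X, "standardized") <- isTRUE(meta$standardized)
  X
}

#' Serialize a fitted classifier to JSON
#'
#' Coefficients, hyperparameters and convergence metadata for any of the
#' three model classes (training feature matrices are not embedded).
#'
#' @param model an `lrc_model`, `rlr_model` or `svm_model`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  out <- if (inherits(model, "lrc_model")) {
    list(type = "lrc", dual_coefficients = model$dual_coefficients,
         offset = model$offset, threshold = model$threshold,
         intercept = model$intercept, n = model$n,
         rank_used = model$rank_used)
  } else if (inherits(model, "rlr_model")) {
    list(type = "rlr", intercept = model$intercept,
         coefficients = model$coefficients, lambda = model$lambda,
         alpha = model$alpha, converged = model$converged,
         npasses = model$npasses, backend = model$backend)
  } else if (inherits(model, "svm_model")) {
    list(type = "svm", dual_coefficients = model$dual_coefficients,
         alpha = model$alpha, b = model$b, C = model$C, mode = model$mode,
         converged = model$converged, iterations = model$iterations,
         gap = model$gap, n = model$n)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a CV grid-search trace to CSV
#' @param cv a `cv_result` from [kfold_grid_search()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_cv_trace_csv <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  k <- ncol(cv$fold_accuracies)
  tab <- data.frame(
    value = rep(cv$grid, k),
    fold = rep(seq_len(k), each = length(cv$grid)),
    accuracy = as.vector(cv$fold_accuracies),
    selected = rep(cv$grid, k) == cv$selected_value)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a split plan to JSON for audit
#' @param plan a `split_plan` from [make_split()].
#' @param path output JSON.
#' @return `path`, invisibly.
#' @export
write_split_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a component-selection trace to CSV (m, accuracy)
#' @param trace a `component_trace`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_component_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "component_trace"))
  utils::write.csv(
    data.frame(m = seq_along(trace$accuracy), accuracy = trace$accuracy,
               cv_accuracy = trace$cv_accuracy,
               best = seq_along(trace$accuracy) == trace$best_count),
    path, row.names = FALSE)
  invisible(path)
}

#' Plot mean accuracy against training sample size
#'
#' One line per method, error bars at one standard deviation — the standard
#' reading view of the experiment-1 aggregate.
#'
#' @param agg output of [aggregate_cells()], restricted or faceted by the
#'   caller to a single dimension.
#' @param dimension which mask dimension to plot (default: smallest present).
#' @param ... passed to [graphics::matplot()].
#' @return the plotted data, invisibly.
#' @export
plot_accuracy_vs_size <- function(agg, dimension = min(agg$dimension), ...) {
  d <- agg[agg$dimension == dimension, ]
  methods <- sort(unique(d$method))
  sizes <- sort(unique(d$sample_size))
  m <- sapply(methods, function(meth) {
    d$mean_accuracy[d$method == meth][order(d$sample_size[d$method == meth])]
  })
  graphics::matplot(sizes, m, type = "b", pch = 19, lty = 1,
                    xlab = "training sample size",
                    ylab = "mean test accuracy",
                    main = sprintf("%d voxels", dimension), ...)
  graphics::legend("bottomright", legend = methods, col = seq_along(methods),
                   pch = 19, lty = 1, bty = "n")
  for (j in seq_along(methods)) {
    dd <- d[d$method == methods[j], ]
    dd <- dd[order(dd$sample_size), ]
    graphics::arrows(dd$sample_size, dd$mean_accuracy - dd$sd_accuracy,
                     dd$sample_size, dd$mean_accuracy + dd$sd_accuracy,
                     angle = 90, code = 3, length = 0.03,
                     col = j)
  }
  invisible(d)
}
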