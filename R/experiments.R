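# Experiment drivers over the (sample size x dimension x method x iteration)
# grid, with conditioning diagnostics and aggregation.
#
# All randomness flows from a single master seed through derive_seed(), one
# child seed per (purpose, cell, iteration) coordinate, so any execution
# order yields identical results. The test set is drawn once per study seed
# and is never touched by training draws or cross-validation.

#' Configure a study
#'
#' Desk-scale defaults: a 32^3 grid standing in for the full-resolution brain,
#' four nested masks proportional to the reference 50K/150K/310K/750K
#' dimensions, the 20..210 sample-size ladder, a fixed balanced 50 + 50 test
#' set, and 20 iterations per cell.
#'
#' All physical lengths are stated in millimetres and converted to voxels via
#' the grid scale: the grid spans a fixed 150 mm field of view, so a 32^3 grid
#' has ~4.7 mm voxels, the 4 mm smoothing kernel is ~0.85 voxels and the
#' 9.4 mm-radius atrophy sphere (~ hippocampal volume) covers ~33 voxels.
#' Scaling lengths together keeps the synthetic study in the same statistical
#' regime as the full-resolution problem (many more effective voxel degrees of
#' freedom than subjects at every mask).
#'
#' @param seed master seed.
#' @param grid_dims integer length-3 grid dimensions.
#' @param field_of_view_mm physical extent of the grid's first axis; fixes the
#'   voxel size as `field_of_view_mm / grid_dims[1]`.
#' @param mask_ratios four increasing mask-size fractions.
#' @param sample_sizes even training sizes.
#' @param thresholds four template thresholds.
#' @param n_iterations iterations per cell.
#' @param methods subset of `"lrc"`, `"rlr"`, `"svm_soft"`, `"svm_hard"`.
#' @param n_cn,n_ad cohort sizes per class.
#' @param effect_size,noise_sd cohort generator settings (see
#'   [cohort_config()]).
#' @param smoothing_fwhm_mm FWHM of the noise-smoothing kernel, in mm.
#' @param effect_radius_mm radius of the spherical atrophy region, in mm.
#' @param n_test_per_class per-class size of the fixed test set.
#' @param grids hyperparameter grids (list with `lambda`, `C`).
#' @param cv_k folds for the grid search.
#' @param standardize `"pooled"` (whole-sample voxel-wise statistics, the
#'   reference preprocessing; default) or `"train"` (leakage-safe: fitted on
#'   training rows only).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              grid_dims = c(32L, 32L, 32L),
                              field_of_view_mm = 150,
                              mask_ratios = default_mask_ratios(),
                              sample_sizes = c(20L, 30L, 40L, 50L, 60L, 90L,
                                               120L, 150L, 180L, 210L),
                              thresholds = TEMPLATE_THRESHOLDS,
                              n_iterations = 20L,
                              methods = c("lrc", "rlr", "svm_soft"),
                              n_cn = 160L, n_ad = 160L,
                              effect_size = 1, noise_sd = 1,
                              smoothing_fwhm_mm = 4,
                              effect_radius_mm = 9.4,
                              n_test_per_class = 50L,
                              grids = default_grids(),
                              cv_k = 10L,
                              standardize = c("pooled", "train")) {
  standardize <- match.arg(standardize)
  voxel_size_mm <- field_of_view_mm / grid_dims[1]
  smoothing_fwhm_vox <- smoothing_fwhm_mm / voxel_size_mm
  effect_radius_vox <- effect_radius_mm / voxel_size_mm
  stopifnot(all(sample_sizes %% 2 == 0), all(thresholds >= 0),
            all(thresholds <= 1), n_iterations >= 1,
            all(methods %in% c("lrc", "rlr", "svm_soft", "svm_hard")))
  need <- n_test_per_class + max(sample_sizes) / 2
  if (n_cn < need || n_ad < need) {
    stop(sprintf("cohort too small: need %d per class for test + largest training size",
                 need))
  }
  structure(list(seed = as.integer(seed), grid_dims = as.integer(grid_dims),
                 field_of_view_mm = field_of_view_mm,
                 voxel_size_mm = voxel_size_mm, mask_ratios = mask_ratios,
                 sample_sizes = as.integer(sample_sizes),
                 thresholds = thresholds,
                 n_iterations = as.integer(n_iterations), methods = methods,
                 n_cn = as.integer(n_cn), n_ad = as.integer(n_ad),
                 effect_size = effect_size, noise_sd = noise_sd,
                 smoothing_fwhm_vox = smoothing_fwhm_vox,
                 effect_radius_vox = effect_radius_vox,
                 n_test_per_class = as.integer(n_test_per_class),
                 grids = grids, cv_k = as.integer(cv_k),
                 standardize = standardize),
            class = "experiment_config")
}

#' Materialize the study: template, cohort, masks, feature matrix
#'
#' Generates the template and cohort for a config, thresholds the template at
#' all four levels, and vectorizes the cohort once under the largest mask;
#' smaller masks are column subsets (nesting makes this exact).
#'
#' @param config an [experiment_config()].
#' @return object of class `study`: `cohort`, `template`, `masks` (by
#'   threshold, decreasing voxel count), `X_full` (cohort x largest mask),
#'   `labels`, `col_index` (per-threshold column indices into `X_full`),
#'   `config`.
#' @export
build_study <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- volume_grid(config$grid_dims, config$voxel_size_mm)
  template <- make_template(grid, config$mask_ratios,
                            seed = derive_seed(config$seed, 1L))
  region <- default_effect_region(template, config$effect_radius_vox)
  cfg <- cohort_config(config$n_cn, config$n_ad, region,
                       effect_size = config$effect_size,
                       noise_sd = config$noise_sd,
                       smoothing_fwhm_vox = config$smoothing_fwhm_vox,
                       seed = derive_seed(config$seed, 2L))
  cohort <- simulate_cohort(template, cfg)
  masks <- lapply(config$thresholds, threshold_mask, template = template)
  names(masks) <- as.character(config$thresholds)
  largest <- which.max(vapply(masks, mask_size, integer(1)))
  vec <- vectorize(cohort, masks[[largest]])
  col_index <- lapply(masks, function(m) {
    match(m$linear_index, masks[[largest]]$linear_index)
  })
  structure(list(cohort = cohort, template = template, masks = masks,
                 X_full = vec$X, labels = vec$y, col_index = col_index,
                 config = config),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("<study %d subjects, masks %s voxels>\n", nrow(x$X_full),
              paste(vapply(x$masks, mask_size, integer(1)), collapse = "/")))
  invisible(x)
}

standardize_cell <- function(study, train_ids, test_ids, cols) {
  Xtr <- study$X_full[train_ids, cols, drop = FALSE]
  Xte <- study$X_full[test_ids, cols, drop = FALSE]
  if (study$config$standardize == "pooled") {
    std <- fit_standardizer(study$X_full[, cols, drop = FALSE])
  } else {
    std <- fit_standardizer(Xtr)
  }
  list(train = apply_standardizer(std, Xtr),
       test = apply_standardizer(std, Xte))
}

fit_cell_method <- function(method, Xtr, ytr, config, cv_seed) {
  if (method == "lrc") {
    list(model = fit_lrc(linear_kernel(Xtr), ytr, X_train = Xtr),
         selected = NA_real_)
  } else if (method == "rlr") {
    cv <- kfold_grid_search(Xtr, ytr, "rlr", grid = config$grids$lambda,
                            k = config$cv_k, seed = cv_seed)
    list(model = cv$model, selected = cv$selected_value)
  } else if (method == "svm_soft") {
    cv <- kfold_grid_search(Xtr, ytr, "svm", grid = config$grids$C,
                            k = config$cv_k, seed = cv_seed)
    list(model = cv$model, selected = cv$selected_value)
  } else if (method == "svm_hard") {
    Xs <- Xtr
    attr(Xs, "standardized") <- TRUE
    list(model = fit_svm(linear_kernel(Xs), ytr, C = hard_margin_C(),
                         X_train = Xtr),
         selected = hard_margin_C())
  } else {
    stop("unknown method: ", method)
  }
}

#' Run Experiment 1: accuracy across sample sizes and dimensions
#'
#' For every (sample size, threshold, iteration): draw a balanced training
#' sample disjoint from the fixed test set, standardize, fit each method
#' (with 10-fold CV grid search for rlr / soft-margin SVM), and evaluate on
#' the fixed test set. Also records the training-kernel conditioning of each
#' cell.
#'
#' @param config an [experiment_config()].
#' @param study optional pre-built [build_study()] result (rebuilt otherwise).
#' @return data.frame of cells: `sample_size`, `threshold`, `dimension`,
#'   `method`, `iteration`, `accuracy`, `selected`, `rank`,
#'   `condition_number`.
#' @export
run_experiment1 <- function(config, study = NULL) {
  if (is.null(study)) study <- build_study(config)
  study_seed <- derive_seed(config$seed, 3L)
  rows <- list()
  for (si in seq_along(config$sample_sizes)) {
    n <- config$sample_sizes[si]
    for (ti in seq_along(config$thresholds)) {
      cols <- study$col_index[[ti]]
      for (it in seq_len(config$n_iterations)) {
        split <- make_split(study$labels, config$n_test_per_class, n,
                            study_seed, derive_seed(config$seed, 4L, si, it))
        Xs <- standardize_cell(study, split$train_ids, split$test_ids, cols)
        ytr <- study$labels[split$train_ids]
        yte <- study$labels[split$test_ids]
        crep <- svd_conditioning(linear_kernel(Xs$train))
        for (method in config$methods) {
          fitres <- fit_cell_method(method, Xs$train, ytr, config,
                                    derive_seed(config$seed, 5L, si, ti, it))
          ev <- evaluate_on_test(fitres$model, Xs$test, yte)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_size = n, threshold = config$thresholds[ti],
            dimension = length(cols), method = method, iteration = it,
            accuracy = ev$accuracy, selected = fitres$selected,
            rank = crep$rank, condition_number = crep$condition_number)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_iterations") <- config$n_iterations
  class(out) <- c("experiment_cells", class(out))
  out
}

#' Run Experiment 2: kernel conditioning across the grid
#'
#' One conditioning report per (sample size, threshold, iteration) training
#' kernel; full spectra are archived when `keep_spectra = TRUE`.
#'
#' @param config an [experiment_config()].
#' @param study optional pre-built study.
#' @param keep_spectra archive the full `conditioning_report`s as the
#'   `reports` attribute.
#' @return data.frame with `sample_size`, `threshold`, `dimension`,
#'   `iteration`, `rank`, `condition_number`, `reciprocal_condition`.
#' @export
run_experiment2 <- function(config, study = NULL, keep_spectra = FALSE) {
  if (is.null(study)) study <- build_study(config)
  study_seed <- derive_seed(config$seed, 3L)
  rows <- list()
  reports <- list()
  for (si in seq_along(config$sample_sizes)) {
    n <- config$sample_sizes[si]
    for (ti in seq_along(config$thresholds)) {
      cols <- study$col_index[[ti]]
      for (it in seq_len(config$n_iterations)) {
        split <- make_split(study$labels, config$n_test_per_class, n,
                            study_seed, derive_seed(config$seed, 4L, si, it))
        Xs <- standardize_cell(study, split$train_ids, split$test_ids, cols)
        crep <- svd_conditioning(linear_kernel(Xs$train))
        key <- sprintf("n%d_t%d_i%d", n, ti, it)
        if (keep_spectra) reports[[key]] <- crep
        rows[[length(rows) + 1L]] <- data.frame(
          sample_size = n, threshold = config$thresholds[ti],
          dimension = length(cols), iteration = it, rank = crep$rank,
          condition_number = crep$condition_number,
          reciprocal_condition = crep$reciprocal_condition)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (keep_spectra) attr(out, "reports") <- reports
  attr(out, "n_iterations") <- config$n_iterations
  out
}

#' Run Experiment 3: voxel space versus principal-component space
#'
#' At the largest mask and the largest sample size, each iteration fits all
#' methods in voxel space and in PC space (incremental component selection),
#' on the same training draw.
#'
#' @param config an [experiment_config()]; `sample_sizes` is reduced to its
#'   maximum and `thresholds` to the largest-mask threshold.
#' @param study optional pre-built study.
#' @param selector component selector, see
#'   [incremental_component_accuracy()].
#' @return data.frame with `iteration`, `method`, `space` (voxel / pc),
#'   `accuracy`, `best_count` (NA for voxel space).
#' @export
run_experiment3 <- function(config, study = NULL,
                            selector = c("test_max", "cv")) {
  selector <- match.arg(selector)
  if (is.null(study)) study <- build_study(config)
  n <- max(config$sample_sizes)
  ti <- which.max(vapply(study$masks, mask_size, integer(1)))
  cols <- study$col_index[[ti]]
  study_seed <- derive_seed(config$seed, 3L)
  si <- which(config$sample_sizes == n)
  methods <- sub("^svm_soft$", "svm", setdiff(config$methods, "svm_hard"))
  rows <- list()
  for (it in seq_len(config$n_iterations)) {
    split <- make_split(study$labels, config$n_test_per_class, n,
                        study_seed, derive_seed(config$seed, 4L, si, it))
    Xs <- standardize_cell(study, split$train_ids, split$test_ids, cols)
    ytr <- study$labels[split$train_ids]
    yte <- study$labels[split$test_ids]
    proj <- pca_fit(Xs$train)
    Ste <- pca_transform(proj, Xs$test)
    for (method in methods) {
      cfg_method <- if (method == "svm") "svm_soft" else method
      fitres <- fit_cell_method(cfg_method, Xs$train, ytr, config,
                                derive_seed(config$seed, 5L, si, ti, it))
      vox_acc <- evaluate_on_test(fitres$model, Xs$test, yte)$accuracy
      grid <- if (method == "rlr") config$grids$lambda else config$grids$C
      trace <- incremental_component_accuracy(
        proj$scores, ytr, Ste, yte, method = method, grid = grid,
        cv_seed = derive_seed(config$seed, 6L, si, it), selector = selector)
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = it, method = method,
        space = c("voxel", "pc"),
        accuracy = c(vox_acc, trace$best_accuracy),
        best_count = c(NA_integer_, trace$best_count))
    }
  }
  do.call(rbind, rows)
}

#' Run the supplementary hard- versus soft-margin comparison
#'
#' Same design as Experiment 1 restricted to the smallest and largest masks,
#' with methods `svm_soft` (CV-tuned C) and `svm_hard` (C = 1e6).
#'
#' @param config an [experiment_config()].
#' @param study optional pre-built study.
#' @return an `experiment_cells` data.frame (as [run_experiment1()]).
#' @export
run_experiment_supp <- function(config, study = NULL) {
  sizes <- vapply(seq_along(config$thresholds), function(ti) {
    if (is.null(study)) NA_integer_ else mask_size(study$masks[[ti]])
  }, integer(1))
  keep <- if (is.null(study)) {
    c(which.max(config$thresholds), which.min(config$thresholds))
  } else {
    c(which.min(sizes), which.max(sizes))
  }
  cfg <- config
  cfg$thresholds <- config$thresholds[sort(unique(keep))]
  cfg$methods <- c("svm_soft", "svm_hard")
  if (!is.null(study)) {
    study$col_index <- study$col_index[sort(unique(keep))]
    study$masks <- study$masks[sort(unique(keep))]
  }
  run_experiment1(cfg, study)
}

#' Aggregate experiment cells
#'
#' Mean, standard deviation and quartiles of accuracy per
#' (sample size, dimension, method), plus median condition number and the
#' range of ranks per (sample size, dimension). Errors if any cell is
#' incomplete.
#'
#' @param cells output of [run_experiment1()] / [run_experiment_supp()].
#' @return data.frame, one row per (sample_size, dimension, method).
#' @export
aggregate_cells <- function(cells) {
  n_iter <- attr(cells, "n_iterations")
  key <- interaction(cells$sample_size, cells$dimension, cells$method,
                     drop = TRUE)
  cnt <- table(key)
  if (!is.null(n_iter) && any(cnt != n_iter)) {
    bad <- names(cnt)[cnt != n_iter]
    stop("incomplete cells: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- do.call(rbind, lapply(split(cells, key), function(g) {
    q <- stats::quantile(g$accuracy, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(sample_size = g$sample_size[1], dimension = g$dimension[1],
               method = g$method[1], n = nrow(g),
               mean_accuracy = mean(g$accuracy),
               sd_accuracy = stats::sd(g$accuracy),
               q25 = q[1], median = q[2], q75 = q[3],
               median_condition = stats::median(g$condition_number),
               min_rank = min(g$rank), max_rank = max(g$rank))
  }))
  rownames(out) <- NULL
  out[order(out$dimension, out$sample_size, out$method), ]
}
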