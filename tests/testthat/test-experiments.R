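# Experiment drivers: bookkeeping, determinism, aggregation.

small_cfg <- function(seed = 7) {
  experiment_config(
    seed = seed, grid_dims = c(12L, 12L, 12L),
    sample_sizes = c(16L, 24L), thresholds = c(0.86, 0.2),
    n_iterations = 2L, n_cn = 40L, n_ad = 40L, n_test_per_class = 12L,
    grids = list(lambda = c(0.01, 1), C = c(0.001, 0.1)), cv_k = 4L)
}

test_that("config validation enforces sizes and cohort feasibility", {
  expect_error(experiment_config(sample_sizes = c(21L, 30L)), "sample_sizes")
  expect_error(experiment_config(n_cn = 60L, n_ad = 60L), "cohort too small")
  expect_error(experiment_config(methods = "nope"), "methods")
  cfg <- experiment_config()
  expect_equal(cfg$voxel_size_mm, 150 / 32)
  expect_equal(cfg$smoothing_fwhm_vox, 4 / (150 / 32))
})

test_that("build_study assembles nested masks and a shared feature matrix", {
  study <- build_study(small_cfg())
  expect_equal(nrow(study$X_full), 80)
  sizes <- vapply(study$masks, mask_size, integer(1))
  expect_equal(ncol(study$X_full), max(sizes))
  small_cols <- study$col_index[[which.min(sizes)]]
  expect_false(any(is.na(small_cols)))
  expect_equal(length(small_cols), min(sizes))
})

test_that("experiment 1 produces the full cell grid deterministically", {
  cfg <- small_cfg()
  study <- build_study(cfg)
  cells <- run_experiment1(cfg, study)
  # sizes x thresholds x methods x iterations
  expect_equal(nrow(cells), 2 * 2 * 3 * 2)
  expect_true(all(cells$accuracy >= 0 & cells$accuracy <= 1))
  expect_true(all(cells$dimension %in%
                    vapply(study$masks, mask_size, integer(1))))
  expect_true(all(is.na(cells$selected[cells$method == "lrc"])))
  expect_true(all(!is.na(cells$selected[cells$method != "lrc"])))
  cells2 <- run_experiment1(cfg, build_study(cfg))
  expect_identical(cells, cells2)
})

test_that("experiment 2 reports conditioning for every cell", {
  cfg <- small_cfg()
  study <- build_study(cfg)
  e2 <- run_experiment2(cfg, study, keep_spectra = TRUE)
  expect_equal(nrow(e2), 2 * 2 * 2)
  expect_true(all(is.finite(e2$condition_number)))
  expect_true(all(e2$rank == e2$sample_size))  # full rank on generic data
  reports <- attr(e2, "reports")
  expect_length(reports, nrow(e2))
  expect_s3_class(reports[[1]], "conditioning_report")
})

test_that("the supplementary comparison runs hard- and soft-margin SVMs", {
  cfg <- small_cfg()
  cfg$sample_sizes <- 16L
  cfg$n_iterations <- 1L
  supp <- run_experiment_supp(cfg)
  expect_setequal(unique(supp$method), c("svm_soft", "svm_hard"))
  expect_equal(nrow(supp), 1 * 2 * 2 * 1)
  expect_true(all(supp$selected[supp$method == "svm_hard"] == hard_margin_C()))
})

test_that("experiment 3 pairs voxel and PC rows per iteration and method", {
  cfg <- small_cfg()
  cfg$n_iterations <- 1L
  e3 <- run_experiment3(cfg)
  expect_equal(nrow(e3), 1 * 3 * 2)
  expect_setequal(unique(e3$space), c("voxel", "pc"))
  expect_true(all(!is.na(e3$best_count[e3$space == "pc"])))
})

test_that("aggregation computes means, sds, quartiles and flags gaps", {
  cells <- data.frame(
    sample_size = rep(10, 4), threshold = 0.2, dimension = rep(50, 4),
    method = rep(c("lrc", "rlr"), each = 2), iteration = rep(1:2, 2),
    accuracy = c(0.8, 0.9, 0.7, 0.7), selected = NA,
    rank = 10, condition_number = c(2, 4, 2, 4))
  attr(cells, "n_iterations") <- 2L
  agg <- aggregate_cells(cells)
  expect_equal(agg$mean_accuracy[agg$method == "lrc"], 0.85)
  expect_equal(agg$sd_accuracy[agg$method == "rlr"], 0)
  expect_equal(agg$median_condition, c(3, 3))
  q <- quantile(c(0.8, 0.9), c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(unlist(agg[agg$method == "lrc", c("q25", "median", "q75")]),
               q, ignore_attr = TRUE)
  broken <- cells[-1, ]
  attr(broken, "n_iterations") <- 2L
  expect_error(aggregate_cells(broken), "incomplete")
})

test_that("pooled and train-only standardization modes both run", {
  cfg <- small_cfg()
  cfg$sample_sizes <- 16L
  cfg$thresholds <- 0.86
  cfg$n_iterations <- 1L
  cfg$methods <- "lrc"
  cells_pooled <- run_experiment1(cfg)
  cfg$standardize <- "train"
  cells_train <- run_experiment1(cfg)
  expect_equal(cells_train$rank, cells_train$sample_size - 1L)  # centering
  expect_equal(cells_pooled$rank, cells_pooled$sample_size)
})
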