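# Synthetic gray-matter cohort generator.

test_that("volume_grid validates its invariants", {
  g <- volume_grid(c(16, 12, 10), 2)
  expect_s3_class(g, "volume_grid")
  expect_equal(n_voxels(g), 16 * 12 * 10)
  expect_error(volume_grid(c(4, 16, 16)), "dims")
  expect_error(volume_grid(c(16, 16, 16), 0), "positive")
})

test_that("templates hit the target mask sizes, nest, and are deterministic", {
  grid <- volume_grid(c(32, 32, 32))
  tpl <- make_template(grid, seed = 7)
  expect_true(all(tpl$values >= 0 & tpl$values <= 1))
  counts <- vapply(tpl$thresholds, function(t) sum(tpl$values > t), numeric(1))
  expect_true(all(diff(counts) > 0))
  targets <- default_mask_ratios() * n_voxels(grid)
  expect_true(all(abs(counts - targets) / targets <= 0.10))

  # nesting across arbitrary threshold pairs, not only the canonical four
  for (tpair in list(c(0.9, 0.5), c(0.65, 0.2), c(0.4, 0.01))) {
    hi <- which(tpl$values > tpair[1])
    lo <- which(tpl$values > tpair[2])
    expect_true(all(hi %in% lo))
  }

  expect_identical(make_template(grid, seed = 7)$values, tpl$values)
  expect_false(identical(make_template(grid, seed = 8)$values, tpl$values))
})

test_that("template construction rejects bad ratio configurations", {
  grid <- tiny_grid()
  expect_error(make_template(grid, c(0.1, 0.05, 0.3, 0.9)), "increasing")
  expect_error(make_template(grid, c(0.1, 0.2, 0.3, 1.2)), "exceeds")
})

test_that("noiseless subjects show exactly the stated atrophy effect", {
  # effect 0.5 keeps AD densities positive (top-mask baseline > 0.86), so
  # the nonnegativity clip cannot mask the pure effect; a full-unit effect
  # would clip at 0 and the difference would be -baseline instead
  tpl <- tiny_template()
  region <- default_effect_region(tpl, radius_vox = 1.5)
  cfg <- cohort_config(2, 2, region, effect_size = 0.5, noise_sd = 0,
                       smoothing_fwhm_vox = 0, seed = 1)
  cn <- simulate_subject(tpl, cfg, "CN", seed = 5)
  ad <- simulate_subject(tpl, cfg, "AD", seed = 5)
  diff <- ad$values - cn$values
  expect_equal(unname(diff[region]), rep(-0.5, nrow(region)))
  off <- array(TRUE, dim(diff)); off[region] <- FALSE
  expect_true(all(diff[off] == 0))
  # clipping branch: a unit effect bottoms out at zero density
  cfg1 <- cohort_config(2, 2, region, effect_size = 1, noise_sd = 0,
                        smoothing_fwhm_vox = 0, seed = 1)
  ad1 <- simulate_subject(tpl, cfg1, "AD", seed = 5)
  expect_true(all(ad1$values[region] == 0))
})

test_that("the atrophy effect is detectable by a voxel t-test at the stated power", {
  # effect 1, noise 1, n = 100 per class: center-voxel two-sample t-test
  # rejects far below 0.01 (Monte-Carlo power ~ 1 at delta = 1, n = 100)
  tpl <- tiny_template()
  region <- default_effect_region(tpl, radius_vox = 1.5)
  cfg <- cohort_config(100, 100, region, effect_size = 1, noise_sd = 1,
                       smoothing_fwhm_vox = 0.85, seed = 31)
  cohort <- simulate_cohort(tpl, cfg)
  center <- region[which.min(rowSums(sweep(region, 2, colMeans(region))^2)), , drop = FALSE]
  vals <- vapply(cohort$volumes, function(v) v$values[center], numeric(1))
  p <- t.test(vals[cohort$labels == 0], vals[cohort$labels == 1])$p.value
  expect_lt(p, 0.01)
})

test_that("cohorts are reproducible, balanced, and class-symmetric off-region", {
  cohort <- tiny_cohort(n_per_class = 5, seed = 123)
  expect_length(cohort$volumes, 10)
  expect_equal(sum(cohort$labels == 0), 5)
  cohort2 <- tiny_cohort(n_per_class = 5, seed = 123)
  expect_identical(lapply(cohort$volumes, `[[`, "values"),
                   lapply(cohort2$volumes, `[[`, "values"))

  # off-region class-mean difference shrinks toward 0 with n (3 SE band)
  tpl <- tiny_template()
  region <- default_effect_region(tpl, radius_vox = 1.5)
  cfg <- cohort_config(250, 250, region, seed = 77, smoothing_fwhm_vox = 0)
  big <- simulate_cohort(tpl, cfg)
  off_voxel <- matrix(c(2L, 2L, 2L), 1, 3)  # far corner, outside the region
  expect_false(any(apply(region, 1, function(r) all(r == off_voxel[1, ]))))
  v <- vapply(big$volumes, function(x) x$values[off_voxel], numeric(1))
  d <- mean(v[big$labels == 1]) - mean(v[big$labels == 0])
  se <- sqrt(var(v[big$labels == 1]) / 250 + var(v[big$labels == 0]) / 250)
  expect_lt(abs(d), 3 * se)
})

test_that("smoothing increases spatial autocorrelation of the noise", {
  # Monte-Carlo: lag-1 autocorrelation under smoothing exceeds the
  # unsmoothed case in every replicate
  tpl <- tiny_template(n = 16)
  region <- default_effect_region(tpl, radius_vox = 1.5)
  lag1 <- function(fwhm, seed) {
    cfg <- cohort_config(2, 2, region, effect_size = 0, noise_sd = 1,
                         smoothing_fwhm_vox = fwhm, seed = seed)
    v <- simulate_subject(tpl, cfg, "CN", seed = seed)
    noise <- v$values - tpl$values  # clipping distorts, but monotonicity survives
    cor(c(noise[1:15, , ]), c(noise[2:16, , ]))
  }
  for (s in 1:5) {
    expect_gt(lag1(2.5, s), lag1(0, s) + 0.05)
  }
})

test_that("effect regions must survive the top threshold", {
  tpl <- tiny_template()
  bad_region <- matrix(c(1L, 1L, 1L), 1, 3)  # corner voxel: low probability
  expect_error(
    simulate_subject(tpl, cohort_config(2, 2, bad_region, seed = 1), "CN", 1),
    "highest-threshold")
})

test_that("cohorts round-trip through NIfTI + CSV sidecar", {
  cohort <- tiny_cohort(n_per_class = 3, seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "participants.csv")))
  back <- read_cohort(dir)
  expect_equal(back$labels, cohort$labels)
  expect_equal(back$subject_ids, cohort$subject_ids)
  # float32 storage: relative error at the 1e-7 scale
  expect_equal(back$volumes[[2]]$values, cohort$volumes[[2]]$values,
               tolerance = 1e-6)
  expect_equal(back$template$values, cohort$template$values, tolerance = 1e-6)
})
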