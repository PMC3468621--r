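# Shared fixtures, built in code. Everything is seeded; sizes are kept small
# so the whole suite stays inside the time budget.

tiny_grid <- function(n = 12) volume_grid(c(n, n, n))

tiny_template <- function(n = 12, seed = 42) {
  make_template(tiny_grid(n), seed = seed)
}

tiny_cohort <- function(n_per_class = 6, seed = 99, noise_sd = 1,
                        smoothing = 0.85, effect_size = 1, n = 12) {
  tpl <- tiny_template(n = n)
  region <- default_effect_region(tpl, radius_vox = 1.5)
  cfg <- cohort_config(n_per_class, n_per_class, region,
                       effect_size = effect_size, noise_sd = noise_sd,
                       smoothing_fwhm_vox = smoothing, seed = seed)
  simulate_cohort(tpl, cfg)
}

# standardized random feature matrix with an optional class signal
random_problem <- function(n, d, delta = 0, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)[sample(n)]
  X <- matrix(rnorm(n * d), n, d)
  if (delta > 0) {
    k <- max(1L, round(d / 4))
    X[, seq_len(k)] <- X[, seq_len(k)] + delta * y
  }
  rownames(X) <- sprintf("sub-%03d", seq_len(n))
  attr(X, "standardized") <- TRUE
  list(X = X, y = y)
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(x)))
}
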