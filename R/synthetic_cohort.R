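# Synthetic gray-matter cohort generator.
#
# Stands in for an access-restricted clinical cohort: a smooth gray-matter
# probability template whose thresholds carve out nested analysis masks, and
# two subject classes (CN / AD) differing by a spatially localized, spatially
# smooth reduction in gray-matter density, on top of spatially correlated
# noise. The correlated-voxel structure is what keeps the linear kernel
# matrices well conditioned downstream, so it is a first-class feature of the
# generator, not a nuisance.

TEMPLATE_THRESHOLDS <- c(0.86, 0.65, 0.2, 0.0021)

#' Default nested mask-size ratios
#'
#' Proportional to the four dimensions of the reference study design
#' (50K : 150K : 310K : 750K voxels), scaled so that the largest mask covers
#' 95\% of the grid.
#' @return numeric vector of 4 increasing fractions of the grid.
#' @export
default_mask_ratios <- function() c(50, 150, 310, 750) / 750 * 0.95

#' Build a synthetic gray-matter probability template
#'
#' A smooth random field (iid uniform noise smoothed with a Gaussian kernel)
#' is passed through a monotone piecewise-linear rescaling of its empirical
#' quantiles so that thresholding at 0.86 / 0.65 / 0.2 / 0.0021 yields nested
#' masks of prescribed sizes. Monotonicity of the rescaling guarantees exact
#' nesting; calibration on the empirical quantiles makes the mask counts hit
#' the targets up to ties (none, for a continuous field).
#'
#' @param grid a [volume_grid()].
#' @param mask_size_ratios four strictly increasing fractions of the grid that
#'   the masks at thresholds 0.86, 0.65, 0.2, 0.0021 should cover.
#' @param seed integer seed; the template is deterministic given it.
#' @param smooth_fwhm_vox smoothness of the underlying field, in voxels.
#' @return an object of class `probability_template` with fields `grid`,
#'   `values` (3-D array in `[0, 1]`) and `thresholds`.
#' @export
#' @examples
#' tpl <- make_template(volume_grid(c(16, 16, 16)), seed = 1)
#' sapply(tpl$thresholds, function(t) sum(tpl$values > t))
make_template <- function(grid, mask_size_ratios = default_mask_ratios(),
                          seed = 1L, smooth_fwhm_vox = 6) {
  stopifnot(inherits(grid, "volume_grid"))
  r <- as.numeric(mask_size_ratios)
  if (length(r) != 4L || any(r <= 0) || any(diff(r) <= 0)) {
    stop("mask_size_ratios must be four strictly increasing positive fractions")
  }
  if (max(r) > 1) {
    stop(sprintf("largest mask ratio %.3g exceeds the grid (must be <= 1)", max(r)))
  }
  field <- with_seed(seed, array(runif(n_voxels(grid)), grid$dims))
  field <- smooth_gaussian_3d(field, smooth_fwhm_vox)$values
  # Map "fraction of voxels above" -> template value through the anchor points
  # (0,1), (r1,.86), (r2,.65), (r3,.2), (r4,.0021), (1,0); applied to the
  # field's ranks this is a strictly monotone transform.
  p_above <- (rank(-field, ties.method = "first") - 0.5) / length(field)
  anchors_p <- c(0, r, 1)
  anchors_t <- c(1, TEMPLATE_THRESHOLDS, 0)
  vals <- stats::approx(anchors_p, anchors_t, xout = p_above, rule = 2)$y
  dim(vals) <- grid$dims
  structure(list(grid = grid, values = vals, thresholds = TEMPLATE_THRESHOLDS),
            class = "probability_template")
}

#' @export
print.probability_template <- function(x, ...) {
  counts <- vapply(x$thresholds, function(t) sum(x$values > t), numeric(1))
  cat(sprintf("<probability_template %d x %d x %d; mask sizes %s at thresholds %s>\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              paste(counts, collapse = "/"),
              paste(x$thresholds, collapse = "/")))
  invisible(x)
}

#' Configure a synthetic cohort
#'
#' @param n_cn,n_ad numbers of cognitively normal and AD subjects
#'   (`n_cn + n_ad >= 4`).
#' @param effect_region integer matrix (k x 3) of 1-based voxel coordinates
#'   carrying the atrophy effect; must lie inside the template's
#'   highest-threshold mask so informative voxels survive all four masks.
#' @param effect_size mean gray-matter reduction in AD subjects over
#'   `effect_region`, in units of `noise_sd` (absolute density units when
#'   `noise_sd = 0`; the default `noise_sd = 1` makes the readings coincide).
#' @param noise_sd marginal standard deviation of the additive noise field.
#' @param smoothing_fwhm_vox FWHM (voxels) of the Gaussian kernel applied to
#'   the noise; creates the correlated-voxel structure of smoothed
#'   morphometry data. The default 0.85 is the 4 mm kernel expressed in the
#'   ~4.7 mm voxels of the default desk-scale grid (see
#'   [experiment_config()]).
#' @param seed integer master seed for the cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_cn, n_ad, effect_region, effect_size = 1,
                          noise_sd = 1, smoothing_fwhm_vox = 0.85,
                          seed = 1L) {
  n_cn <- as.integer(n_cn); n_ad <- as.integer(n_ad)
  stopifnot(n_cn >= 1, n_ad >= 1, n_cn + n_ad >= 4,
            is.matrix(effect_region), ncol(effect_region) == 3,
            nrow(effect_region) >= 1,
            is.finite(effect_size), noise_sd >= 0, smoothing_fwhm_vox >= 0)
  structure(list(n_cn = n_cn, n_ad = n_ad,
                 effect_region = effect_region,
                 effect_size = effect_size, noise_sd = noise_sd,
                 smoothing_fwhm_vox = smoothing_fwhm_vox,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Pick a spherical effect region inside the highest-threshold mask
#'
#' Centers a sphere of the given radius on the template's maximum-probability
#' voxel, then keeps only voxels above the highest threshold (0.86), so the
#' informative voxels are present at every analysis dimension.
#'
#' @param template a `probability_template`.
#' @param radius_vox sphere radius in voxels.
#' @return integer matrix of voxel coordinates (k x 3).
#' @export
default_effect_region <- function(template, radius_vox = 3) {
  stopifnot(inherits(template, "probability_template"))
  d <- template$grid$dims
  ctr <- arrayInd(which.max(template$values), d)[1, ]
  rng <- lapply(1:3, function(k) {
    seq(max(1L, ctr[k] - ceiling(radius_vox)), min(d[k], ctr[k] + ceiling(radius_vox)))
  })
  coords <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  dist2 <- rowSums((sweep(coords, 2, ctr))^2)
  coords <- coords[dist2 <= radius_vox^2, , drop = FALSE]
  top <- template$values[coords] > max(template$thresholds)
  out <- coords[top, , drop = FALSE]
  if (nrow(out) == 0) stop("no effect-region voxel survives the highest threshold")
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

check_region_in_top_mask <- function(template, cfg) {
  if (any(template$values[cfg$effect_region] <= max(template$thresholds))) {
    stop("effect_region must lie inside the highest-threshold (0.86) mask")
  }
}

#' Simulate one subject's gray-matter map
#'
#' `values = template - effect * 1[effect_region, label == AD] + noise`,
#' clipped at 0, where the noise is iid Gaussian smoothed to
#' `smoothing_fwhm_vox` and rescaled so its marginal standard deviation is
#' exactly `noise_sd`. Deterministic per seed.
#'
#' @param template a `probability_template`.
#' @param cfg a [cohort_config()].
#' @param label `"CN"` or `"AD"`.
#' @param seed integer seed for this subject.
#' @param subject_id character id.
#' @return a [gm_volume()].
#' @export
simulate_subject <- function(template, cfg, label, seed,
                             subject_id = sprintf("S%06d", seed %% 1000000L)) {
  stopifnot(inherits(template, "probability_template"),
            inherits(cfg, "cohort_config"))
  check_region_in_top_mask(template, cfg)
  label <- match.arg(label, c("CN", "AD"))
  vals <- template$values
  if (label == "AD") {
    amp <- cfg$effect_size * if (cfg$noise_sd > 0) cfg$noise_sd else 1
    vals[cfg$effect_region] <- vals[cfg$effect_region] - amp
  }
  if (cfg$noise_sd > 0) {
    noise <- with_seed(seed, array(stats::rnorm(n_voxels(template$grid)),
                                   template$grid$dims))
    sm <- smooth_gaussian_3d(noise, cfg$smoothing_fwhm_vox)
    vals <- vals + sm$values * (cfg$noise_sd / sqrt(sm$kernel_ssq))
  }
  vals[vals < 0] <- 0
  gm_volume(template$grid, vals, subject_id, label)
}

#' Simulate a labelled cohort of gray-matter maps
#'
#' Per-subject seeds are derived from `cfg$seed` with [derive_seed()], so the
#' cohort is bit-identical across runs and insensitive to generation order.
#'
#' @param template a `probability_template`.
#' @param cfg a [cohort_config()].
#' @return an object of class `gm_cohort`: list with `volumes` (list of
#'   [gm_volume()]), `labels` (integer, 0 = CN / 1 = AD), `subject_ids`,
#'   `template`, `config`.
#' @export
simulate_cohort <- function(template, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  labels <- c(rep("CN", cfg$n_cn), rep("AD", cfg$n_ad))
  vols <- vector("list", length(labels))
  ids <- character(length(labels))
  for (i in seq_along(labels)) {
    ids[i] <- sprintf("sub-%04d", i)
    vols[[i]] <- simulate_subject(template, cfg, labels[i],
                                  seed = derive_seed(cfg$seed, 7L, i),
                                  subject_id = ids[i])
  }
  structure(list(volumes = vols,
                 labels = as.integer(labels == "AD"),
                 subject_ids = ids,
                 template = template, config = cfg),
            class = "gm_cohort")
}

#' @export
print.gm_cohort <- function(x, ...) {
  cat(sprintf("<gm_cohort %d subjects (%d CN, %d AD), grid %d x %d x %d>\n",
              length(x$volumes), sum(x$labels == 0), sum(x$labels == 1),
              x$template$grid$dims[1], x$template$grid$dims[2],
              x$template$grid$dims[3]))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus a label sidecar
#'
#' One `.nii.gz` per subject plus `participants.csv` (subject_id,label) and
#' `template.nii.gz`.
#'
#' @param cohort a `gm_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- cohort$template$grid$voxel_size_mm
  write_nifti(cohort$template$values, file.path(dir, "template.nii.gz"), vs)
  for (v in cohort$volumes) {
    write_nifti(v$values, file.path(dir, paste0(v$subject_id, ".nii.gz")), vs)
  }
  utils::write.csv(
    data.frame(subject_id = cohort$subject_ids,
               label = ifelse(cohort$labels == 1, "AD", "CN")),
    file.path(dir, "participants.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `template.nii.gz`, per-subject `.nii.gz`
#'   volumes and `participants.csv`.
#' @return a `gm_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  part <- utils::read.csv(file.path(dir, "participants.csv"),
                          stringsAsFactors = FALSE)
  tpl_raw <- read_nifti(file.path(dir, "template.nii.gz"))
  grid <- volume_grid(dim(tpl_raw$values), tpl_raw$voxel_size_mm)
  template <- structure(list(grid = grid, values = tpl_raw$values,
                             thresholds = TEMPLATE_THRESHOLDS),
                        class = "probability_template")
  vols <- lapply(seq_len(nrow(part)), function(i) {
    v <- read_nifti(file.path(dir, paste0(part$subject_id[i], ".nii.gz")))
    vals <- v$values
    vals[vals < 0] <- 0  # float32 round-off can graze below zero
    gm_volume(grid, vals, part$subject_id[i], part$label[i])
  })
  structure(list(volumes = vols,
                 labels = as.integer(part$label == "AD"),
                 subject_ids = part$subject_id,
                 template = template, config = NULL),
            class = "gm_cohort")
}
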