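#' Define a voxel grid
#'
#' A `volume_grid` fixes the shape of all volumes in a study: integer
#' dimensions and a physical voxel size. Grids are deliberately small by
#' default elsewhere in the package (a 32^3 grid stands in for a full-resolution
#' brain) so the complete experiment grid runs on a desk machine.
#'
#' @param dims integer vector of length 3 (nx, ny, nz), each >= 8.
#' @param voxel_size_mm positive numeric length 1 or 3, physical voxel size.
#' @return an object of class `volume_grid`.
#' @export
#' @examples
#' g <- volume_grid(c(16, 16, 16))
volume_grid <- function(dims, voxel_size_mm = c(1, 1, 1)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims < 8L)) {
    stop("dims must be three integers, each >= 8")
  }
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be three strictly positive numbers")
  }
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %d x %d x %d, voxel %.3g x %.3g x %.3g mm>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Total number of voxels in a grid
#' @param grid a `volume_grid`.
#' @return integer voxel count.
#' @export
n_voxels <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  prod(grid$dims)
}

same_grid <- function(a, b) {
  identical(a$dims, b$dims)
}

#' Smooth a 3-D array with an isotropic Gaussian kernel
#'
#' Circular (periodic) convolution via the FFT. Periodic wrap keeps the
#' smoothed field statistically homogeneous (no variance loss at the
#' boundary), which matters when the smoothed field is noise whose marginal
#' standard deviation must be controlled.
#'
#' @param arr numeric 3-D array.
#' @param fwhm_vox full width at half maximum of the kernel, in voxels.
#'   `0` returns `arr` unchanged.
#' @return list with `values` (smoothed array) and `kernel_ssq` (the sum of
#'   squared kernel weights; smoothing iid unit-variance noise yields marginal
#'   variance `kernel_ssq`).
#' @export
smooth_gaussian_3d <- function(arr, fwhm_vox) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L, fwhm_vox >= 0)
  if (fwhm_vox == 0) {
    return(list(values = arr, kernel_ssq = 1))
  }
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  k1 <- lapply(d, function(n) {
    # wrapped 1-D Gaussian, normalized to sum 1
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    w <- exp(-x^2 / (2 * sigma^2))
    w / sum(w)
  })
  kern <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  dim(kern) <- d
  sm <- Re(fft(fft(arr) * fft(kern), inverse = TRUE)) / prod(d)
  list(values = sm, kernel_ssq = sum(kern^2))
}

#' Construct a gray-matter density volume
#'
#' The synthetic analogue of a modulated, smoothed gray-matter map: a
#' nonnegative scalar field on a grid, carrying a subject id and a class
#' label (`"CN"` or `"AD"`).
#'
#' @param grid a `volume_grid`.
#' @param values numeric 3-D array matching `grid`, finite and nonnegative.
#' @param subject_id character scalar.
#' @param label `"CN"` or `"AD"`.
#' @return an object of class `gm_volume`.
#' @export
gm_volume <- function(grid, values, subject_id, label) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.array(values) || !identical(dim(values), as.integer(grid$dims))) {
    stop("values must be a 3-D array matching the grid dimensions")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("gray-matter densities must be nonnegative")
  label <- match.arg(label, c("CN", "AD"))
  structure(list(grid = grid, values = values,
                 subject_id = as.character(subject_id), label = label),
            class = "gm_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  cat(sprintf("<gm_volume %s [%s] %d x %d x %d, mean %.4f>\n",
              x$subject_id, x$label, x$grid$dims[1], x$grid$dims[2],
              x$grid$dims[3], mean(x$values)))
  invisible(x)
}
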