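# Minimal NIfTI-1 I/O.
#
# No NIfTI package is available in the target environment, so a small
# single-file reader/writer is provided. Scope: 3-D volumes, datatypes
# uint8 / int16 / int32 / float32 / float64, single-file .nii or .nii.gz,
# native or swapped endianness on read, no orientation handling beyond
# pixdim (analysis here is voxel-index based throughout).

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D volume as a NIfTI-1 file
#'
#' @param values numeric 3-D array.
#' @param path output path, `.nii` or `.nii.gz`.
#' @param voxel_size_mm numeric length-3 physical voxel size.
#' @param datatype `"float32"` (default), `"float64"`, or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(values, path, voxel_size_mm = c(1, 1, 1),
                        datatype = c("float32", "float64", "uint8")) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  stopifnot(length(voxel_size_mm) == 3L)
  datatype <- match.arg(datatype)
  code <- switch(datatype, uint8 = 2L, float32 = 16L, float64 = 64L)
  bitpix <- switch(datatype, uint8 = 8L, float32 = 32L, float64 = 64L)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                     # sizeof_hdr
  writeBin(raw(36), con)                            # unused (data_type..session_error, regular, dim_info)
  dimv <- c(3L, dim(values), 1L, 1L, 1L, 1L)
  writeBin(as.integer(dimv), con, size = 2)         # dim[8]
  writeBin(raw(14), con)                            # intent_p1..intent_code
  writeBin(as.integer(c(code, bitpix, 0L)), con, size = 2)  # datatype, bitpix, slice_start
  writeBin(c(0, voxel_size_mm, 1, 1, 1, 1), con, size = 4)  # pixdim[8]
  writeBin(c(352, 1, 0), con, size = 4)             # vox_offset, scl_slope, scl_inter
  writeBin(raw(344 - 120), con)                     # slice_end .. srow_z, intent_name (all zero)
  writeBin(charToRaw("n+1"), con)                   # magic
  writeBin(raw(1), con)
  writeBin(raw(4), con)                             # extension flag = 0
  if (datatype == "uint8") {
    writeBin(as.raw(pmin(pmax(round(values), 0), 255)), con)
  } else {
    writeBin(as.numeric(values), con, size = bitpix / 8)
  }
  invisible(path)
}

#' Read a NIfTI-1 file written as a single `.nii`/`.nii.gz`
#'
#' @param path input path.
#' @return list with `values` (3-D array) and `voxel_size_mm`.
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  rd_i <- function(off, size, n, endian) {
    readBin(hdr[(off + 1):(off + size * n)], "integer",
            n = n, size = size, endian = endian)
  }
  rd_d <- function(off, n, endian) {
    readBin(hdr[(off + 1):(off + 4 * n)], "double",
            n = n, size = 4, endian = endian)
  }
  endian <- "little"
  if (rd_i(0, 4, 1, endian) != 348L) {
    endian <- "big"
    if (rd_i(0, 4, 1, endian) != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop("unsupported NIfTI magic '", magic, "' (need single-file n+1)")
  dimv <- rd_i(40, 2, 8, endian)
  ndim <- dimv[1]
  if (ndim < 3) stop("expected a 3-D volume")
  d3 <- dimv[2:4]
  extra <- if (ndim > 3) prod(pmax(dimv[5:(1 + ndim)], 1L)) else 1L
  if (extra != 1L) stop("only single-volume files are supported")
  datatype <- rd_i(70, 2, 1, endian)
  pixdim <- rd_d(76, 8, endian)
  vox_offset <- rd_d(108, 1, endian)
  scl_slope <- rd_d(112, 1, endian)
  scl_inter <- rd_d(116, 1, endian)
  nvox <- prod(d3)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = FALSE, endian = endian)),
    "4"  = as.numeric(readBin(con, "integer", n = nvox, size = 2, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n = nvox, size = 4, endian = endian)),
    "16" = readBin(con, "double", n = nvox, size = 4, endian = endian),
    "64" = readBin(con, "double", n = nvox, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype)
  )
  if (length(vals) != nvox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  dim(vals) <- d3
  list(values = vals, voxel_size_mm = pixdim[2:4])
}
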