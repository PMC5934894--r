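# Minimal NIfTI-1 I/O (single-file .nii / .nii.gz, 3D volumes).
#
# Only the subset of NIfTI-1 needed for SUV volumes and integer label masks
# is supported: dtypes uint8, int16, int32, uint16, float32, float64; spacing
# taken from the sform rows when sform_code > 0, else from pixdim; scl_slope /
# scl_inter applied on read. Written files use a diagonal sform (spacing on
# the diagonal, origin in the offset column), float32 for real-valued grids
# and int16 for label grids.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Read a 3D NIfTI-1 volume
#'
#' Low-level reader returning the raw voxel grid plus geometry. Most users
#' want [read_suv_image()] or [read_mask()].
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (3D array), `spacing` (mm, length 3),
#'   `origin` (mm, length 3) and `affine` (3x4 voxel-to-mm matrix).
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) {
    stop("NIfTI file not found: ", path, call. = FALSE)
  }
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int32(sizeof_hdr) != 348L) {
      stop("not a NIfTI-1 file (bad header size): ", path, call. = FALSE)
    }
  }
  readBin(con, "raw", 36L)                                   # unused fields
  dim <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "double", 3L, size = 4L, endian = endian)     # intent_p1..p3
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 4L)                                    # slice_end/code/units
  readBin(con, "double", 4L, size = 4L, endian = endian)     # cal_max..toffset
  readBin(con, "integer", 2L, size = 4L, endian = endian)    # glmax, glmin
  readBin(con, "raw", 104L)                                  # descrip, aux_file
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # qform_code
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "double", 6L, size = 4L, endian = endian)     # quaternion fields
  srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16L)                                   # intent_name
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1")) {
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  }

  ndim <- dim[1]
  if (ndim < 3L || any(dim[2:4] < 1L) || (ndim > 3L && any(dim[5:(ndim + 1)] > 1L))) {
    stop("only 3D volumes are supported, got dim = ",
         paste(dim[2:(max(ndim, 3) + 1)], collapse = "x"), call. = FALSE)
  }
  shape <- dim[2:4]

  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) {
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  }
  # skip to the data section
  already <- 348L
  skip <- round(vox_offset) - already
  if (skip > 0) readBin(con, "raw", skip)

  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) {
    stop("truncated NIfTI data section in ", path, call. = FALSE)
  }
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = shape)

  if (sform_code > 0L) {
    affine <- srow
    spacing <- sqrt(colSums(affine[, 1:3, drop = FALSE]^2))
    origin <- affine[, 4]
  } else {
    spacing <- abs(pixdim[2:4])
    origin <- c(0, 0, 0)
    affine <- cbind(diag(spacing), origin)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("non-positive voxel spacing in ", path, call. = FALSE)
  }
  list(data = data, spacing = spacing, origin = origin, affine = affine)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  readBin(rev(b), "integer", 1L, size = 4L, endian = "little")
}

#' Write a 3D volume as NIfTI-1
#'
#' @param data 3D numeric or integer array.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param spacing Voxel edge lengths in mm (length 3, all > 0).
#' @param origin Physical coordinate of voxel (0,0,0) in mm.
#' @param datatype `"float32"` (default for numeric data) or `"int16"`
#'   (default for integer data / label masks).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(data, path, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0), datatype = NULL) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  if (is.null(datatype)) {
    datatype <- if (is.integer(data) || all(data == round(data))) "int16" else "float32"
  }
  code <- switch(datatype, float32 = 16L, int16 = 4L,
                 stop("unsupported write datatype: ", datatype, call. = FALSE))
  size <- switch(datatype, float32 = 4L, int16 = 2L)
  bitpix <- 8L * size

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)

  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                       # sizeof_hdr
  w_raw(36L)                        # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))   # dim
  w_f32(c(0, 0, 0)); w_i16(0L)      # intent
  w_i16(code); w_i16(bitpix); w_i16(0L)
  w_f32(c(1, spacing, 1, 1, 1, 1))  # pixdim (qfac = 1)
  w_f32(352)                        # vox_offset
  w_f32(1); w_f32(0)                # scl_slope, scl_inter
  w_i16(0L); w_raw(1L)              # slice_end, slice_code
  writeBin(as.raw(2L), con)         # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(104L)                       # descrip, aux_file
  w_i16(0L); w_i16(1L)              # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                  # quaternion
  w_f32(c(spacing[1], 0, 0, origin[1]))
  w_f32(c(0, spacing[2], 0, origin[2]))
  w_f32(c(0, 0, spacing[3], origin[3]))
  w_raw(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  w_raw(4L)                         # extension flag

  if (datatype == "int16") {
    writeBin(as.integer(data), con, size = 2L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 4L, endian = "little")
  }
  invisible(path)
}
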