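# Minimal NIfTI-1 I/O.
#
# Only the subset of NIfTI-1 this pipeline needs: single-file .nii (optionally
# gzipped), sform affine, plain numeric datatypes, no extensions. The header
# is the fixed 348-byte NIfTI-1 layout; data start at vox_offset.

NIFTI_HDR_SIZE <- 348L

# datatype code -> (what, size, signed)
.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),  # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),  # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

#' Spatial frame of a volume
#'
#' A `volume_grid` holds the 3-D extents, voxel size in millimetres, and the
#' 4x4 voxel-to-world affine of a volume. Voxel indices are 0-based (i, j, k)
#' in array order; world coordinates are obtained as
#' `affine %*% c(i, j, k, 1)`. Hemisphere membership downstream is defined by
#' the sign of the world x coordinate, never by array index.
#'
#' @param shape integer vector of 3 positive extents.
#' @param voxel_size numeric vector of 3 positive voxel edge lengths (mm).
#' @param affine 4x4 invertible voxel-to-world matrix; default centres the
#'   grid on the world origin with axes scaled by `voxel_size`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(voxel_size) == 3L)
  if (any(shape < 1L)) stop("volume_grid: all extents must be >= 1")
  if (any(voxel_size <= 0)) stop("volume_grid: voxel sizes must be > 0")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("volume_grid: affine must be invertible")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 affine = affine),
            class = "volume_grid")
}

#' @export
format.volume_grid <- function(x, ...) {
  sprintf("<volume_grid %s, voxel %s mm>",
          paste(x$shape, collapse = "x"),
          paste(signif(x$voxel_size, 3), collapse = "x"))
}

#' @export
print.volume_grid <- function(x, ...) cat(format(x), "\n")

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

# world coordinates (n x 3) of 0-based voxel index matrix (n x 3)
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  h <- cbind(ijk, 1)
  t(grid$affine %*% t(h))[, 1:3, drop = FALSE]
}

.read_exact <- function(con, what, n, size, signed = TRUE, endian) {
  out <- readBin(con, what = what, n = n, size = size, signed = signed,
                 endian = endian)
  if (length(out) != n) stop("unexpected end of file")
  out
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`). Supports uint8,
#' int8/16/32, uint16, float32 and float64 data; applies `scl_slope` /
#' `scl_inter` when set; takes the affine from the sform (falling back to
#' pixdim-scaled identity). Byte order is detected from `sizeof_hdr`.
#'
#' @param path file path.
#' @return A list with `data` (3-D or 4-D array; integer storage preserved for
#'   integer datatypes with no scaling), `grid` (a [volume_grid()]) and `tr`
#'   (seconds; `NA` for 3-D volumes).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("read_nifti: no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(hdr_raw) < NIFTI_HDR_SIZE)
    stop("read_nifti: truncated header in ", path)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sz != NIFTI_HDR_SIZE) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sz != NIFTI_HDR_SIZE)
      stop("read_nifti: not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n = n, size = 2L,
                                     endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "numeric", n = n, size = 4L,
                                     endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("read_nifti: bad magic string in ", path)
  dim_ <- rd_i16(40L, 8L)
  ndim <- dim_[1]
  if (!ndim %in% c(3L, 4L))
    stop("read_nifti: only 3-D/4-D volumes supported, got ndim=", ndim)
  dims <- dim_[2:(1 + ndim)]
  if (any(dims < 1L)) stop("read_nifti: non-positive dimension in header")
  datatype <- rd_i16(70L, 1L)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("read_nifti: unsupported datatype code ", datatype)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  sform_code <- rd_i16(254L, 1L)
  affine <- NULL
  if (sform_code > 0L) {
    affine <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L),
                    c(0, 0, 0, 1))
  }
  # skip from end of header to vox_offset
  skip <- as.integer(round(vox_offset)) - NIFTI_HDR_SIZE
  if (skip < 0L) stop("read_nifti: vox_offset precedes header end")
  if (skip > 0L) {
    got <- readBin(con, "raw", n = skip)
    if (length(got) != skip) stop("read_nifti: truncated file: ", path)
  }
  n_vox <- prod(as.double(dims))
  vals <- readBin(con, what = dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n_vox)
    stop("read_nifti: truncated file: ", path,
         " (expected ", n_vox, " voxels, got ", length(vals), ")")
  scaled <- is.finite(scl_slope) && scl_slope != 0 &&
    !(scl_slope == 1 && scl_inter == 0)
  if (scaled) vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = dims)
  voxel_size <- abs(pixdim[2:4])
  if (any(voxel_size <= 0)) voxel_size <- pmax(voxel_size, 1)
  grid <- volume_grid(dims[1:3], voxel_size, affine)
  tr <- if (ndim == 4L) pixdim[5] else NA_real_
  list(data = data, grid = grid, tr = tr)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D or 4-D array as a single-file NIfTI-1 image. Integer arrays
#' are stored as int32, doubles as float64; the grid's affine is stored in the
#' sform. Paths ending in `.gz` are gzip-compressed.
#'
#' @param data 3-D or 4-D numeric or integer array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid a [volume_grid()] matching `dim(data)[1:3]`.
#' @param tr repetition time in seconds, stored in `pixdim[5]` for 4-D data.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, grid, tr = 1) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("write_nifti: data must be 3-D or 4-D")
  if (!identical(as.integer(dim(data)[1:3]), grid$shape))
    stop("write_nifti: data dimensions do not match grid shape")
  int_store <- is.integer(data)
  datatype <- if (int_store) 8L else 64L
  bitpix <- if (int_store) 32L else 64L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                                endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                                endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L,
                                endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  dims <- rep(1L, 8L)
  dims[1] <- nd
  dims[2:(1 + nd)] <- dim(data)
  pixdim <- rep(0, 8)
  pixdim[1] <- 1
  pixdim[2:4] <- grid$voxel_size
  pixdim[5] <- if (nd == 4L) tr else 0

  w_i32(NIFTI_HDR_SIZE)        # sizeof_hdr
  w_raw(36L)                   # data_type..dim_info
  w_i16(dims)                  # dim[8]
  w_f32(c(0, 0, 0))            # intent_p1..p3
  w_i16(c(0L, datatype, bitpix, 0L)) # intent_code, datatype, bitpix, slice_start
  w_f32(pixdim)                # pixdim[8]
  w_f32(352)                   # vox_offset
  w_f32(c(1, 0))               # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)         # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))         # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))             # glmax, glmin
  w_raw(80L + 24L)             # descrip, aux_file
  w_i16(c(0L, 1L))             # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))             # quatern, qoffset
  w_f32(grid$affine[1, ])      # srow_x
  w_f32(grid$affine[2, ])      # srow_y
  w_f32(grid$affine[3, ])      # srow_z
  w_raw(16L)                   # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1L)  # magic
  w_raw(4L)                    # extension flag
  if (int_store) {
    w_i32(as.vector(data))
  } else {
    writeBin(as.numeric(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}
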