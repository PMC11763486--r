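# Masked time-series extraction and the WM-GM Pearson connectome.

#' Extract masked voxel time series
#'
#' Returns one row per `TRUE` voxel of the mask, in canonical order:
#' lexicographic by 0-based (i, j, k). The `voxel_index` attribute records
#' that order so rows can be scattered back into a volume.
#'
#' @param run a `bold_run`.
#' @param mask a `binary_mask` (or `group_mask`) on the same grid.
#' @return A `timeseries_matrix`: numeric voxel x time matrix with attributes
#'   `voxel_index` (n x 3 matrix of 0-based indices) and `tissue`.
#' @export
extract_timeseries <- function(run, mask) {
  if (inherits(mask, "group_mask")) mask <- mask$mask
  stopifnot(inherits(run, "bold_run"), inherits(mask, "binary_mask"))
  if (!grids_equal(run$grid, mask$grid))
    stop("extract_timeseries: run and mask grids differ")
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("extract_timeseries: empty mask")
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  sh <- dim(run$data)[1:3]
  tt <- dim(run$data)[4]
  lin <- idx[, 1] + sh[1] * ((idx[, 2] - 1L) + sh[2] * (idx[, 3] - 1L))
  vals <- matrix(run$data, prod(sh), tt)[lin, , drop = FALSE]
  structure(vals,
            voxel_index = unname(idx) - 1L,
            tissue = mask$tissue,
            class = c("timeseries_matrix", "matrix", "array"))
}

#' Scatter time-series rows back into a 4-D volume
#'
#' Inverse of [extract_timeseries()]: writes each row at its voxel index,
#' leaving other voxels at `fill`.
#'
#' @param ts a `timeseries_matrix`.
#' @param grid the target [volume_grid()].
#' @param fill value for voxels outside the mask.
#' @return A 4-D array.
#' @export
scatter_timeseries <- function(ts, grid, fill = 0) {
  idx <- attr(ts, "voxel_index")
  sh <- grid$shape
  tt <- ncol(ts)
  out <- array(fill, dim = c(sh, tt))
  lin <- idx[, 1] + 1L + sh[1] * (idx[, 2] + sh[2] * idx[, 3])
  m <- matrix(out, prod(sh), tt)
  m[lin, ] <- ts
  array(m, dim = c(sh, tt))
}

# rows standardized to mean 0, sd 1; errors on zero-variance rows,
# naming their voxel coordinates when available
.standardize_rows <- function(x, label = "matrix") {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2) / (ncol(x) - 1))
  bad <- which(s < .Machine$double.eps * 1e3)
  if (length(bad)) {
    idx <- attr(x, "voxel_index")
    where <- if (!is.null(idx))
      paste(apply(idx[bad, , drop = FALSE], 1, paste, collapse = ","),
            collapse = "; ")
    else paste(bad, collapse = ", ")
    stop("pearson_fc: zero-variance row(s) in ", label, " at voxel(s): ",
         where)
  }
  xc / s
}

#' WM-GM Pearson functional connectome
#'
#' Entry (i, j) is the Pearson correlation between WM row i and GM row j.
#' Computed in double precision with explicit mean/SD per row; values are
#' clamped to [-1, 1] against floating-point overshoot.
#'
#' @param wm,gm `timeseries_matrix` objects with equal time extents.
#' @return An `fc_matrix`: WM x GM correlation matrix with `row_index` /
#'   `col_index` attributes carrying the voxel orders.
#' @export
pearson_fc <- function(wm, gm) {
  if (ncol(wm) != ncol(gm))
    stop("pearson_fc: time extents differ (", ncol(wm), " vs ", ncol(gm), ")")
  zw <- .standardize_rows(wm, "WM")
  zg <- .standardize_rows(gm, "GM")
  r <- tcrossprod(zw, zg) / (ncol(wm) - 1)
  r <- pmin(pmax(r, -1), 1)
  structure(r,
            row_index = attr(wm, "voxel_index"),
            col_index = attr(gm, "voxel_index"),
            class = c("fc_matrix", "matrix", "array"))
}

#' Average connectomes across subjects
#'
#' Element-wise arithmetic mean of per-subject FC matrices (the group
#' connection matrix). Optionally averages Fisher z-transformed values and
#' maps back through tanh.
#'
#' @param fcs list of `fc_matrix` objects with identical shapes and voxel
#'   indices.
#' @param fisher_z average in Fisher z space instead of raw r.
#' @return The group-average `fc_matrix`.
#' @export
average_connectomes <- function(fcs, fisher_z = FALSE) {
  stopifnot(length(fcs) >= 1L)
  ref_dim <- dim(fcs[[1]])
  ref_row <- attr(fcs[[1]], "row_index")
  ref_col <- attr(fcs[[1]], "col_index")
  for (fc in fcs) {
    if (!identical(dim(fc), ref_dim))
      stop("average_connectomes: shape mismatch across subjects")
    if (!identical(attr(fc, "row_index"), ref_row) ||
        !identical(attr(fc, "col_index"), ref_col))
      stop("average_connectomes: voxel index mismatch across subjects")
  }
  if (fisher_z) {
    clip <- function(r) pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    z <- Reduce(`+`, lapply(fcs, function(fc) atanh(clip(fc)))) / length(fcs)
    avg <- tanh(z)
  } else {
    avg <- Reduce(`+`, fcs) / length(fcs)
  }
  avg <- pmin(pmax(avg, -1), 1)
  structure(avg, row_index = ref_row, col_index = ref_col,
            class = c("fc_matrix", "matrix", "array"))
}
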