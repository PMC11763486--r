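# Per-subject signal cleaning and tissue-mask construction.

#' Tissue probability maps
#'
#' Three aligned probability volumes (WM, GM, CSF) on one grid. Values must
#' lie in [0, 1] and sum to 1 per voxel within 0.01.
#'
#' @param wm,gm,csf 3-D probability arrays.
#' @param grid a [volume_grid()].
#' @return An object of class `tissue_probabilities`.
#' @export
tissue_probabilities <- function(wm, gm, csf, grid) {
  for (p in list(wm, gm, csf)) {
    if (!identical(as.integer(dim(p)), grid$shape))
      stop("tissue_probabilities: map does not match grid shape")
    if (any(p < 0 | p > 1))
      stop("tissue_probabilities: values outside [0, 1]")
  }
  tot <- wm + gm + csf
  if (any(abs(tot - 1) > 0.01))
    stop("tissue_probabilities: per-voxel sums outside [0.99, 1.01] at ",
         sum(abs(tot - 1) > 0.01), " voxel(s)")
  structure(list(wm = wm, gm = gm, csf = csf, grid = grid),
            class = "tissue_probabilities")
}

#' Binary tissue mask
#'
#' @param data 3-D logical array.
#' @param grid a [volume_grid()].
#' @param tissue tissue tag (e.g. "wm").
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, grid, tissue = "wm") {
  stopifnot(is.logical(data), length(dim(data)) == 3L)
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("binary_mask: data does not match grid shape")
  structure(list(data = data, grid = grid, tissue = tissue),
            class = "binary_mask")
}

#' Classify voxels into WM/GM/CSF by highest probability
#'
#' Each voxel is assigned to the tissue class with the highest probability.
#' Ties are broken by the fixed priority WM > GM > CSF, so the three masks
#' always partition the grid.
#'
#' @param probs a [tissue_probabilities()].
#' @return A list of three `binary_mask` objects (`wm`, `gm`, `csf`).
#' @export
classify_tissues <- function(probs) {
  stopifnot(inherits(probs, "tissue_probabilities"))
  wm_win <- probs$wm >= probs$gm & probs$wm >= probs$csf
  gm_win <- !wm_win & probs$gm >= probs$csf
  csf_win <- !wm_win & !gm_win
  list(wm = binary_mask(wm_win, probs$grid, "wm"),
       gm = binary_mask(gm_win, probs$grid, "gm"),
       csf = binary_mask(csf_win, probs$grid, "csf"))
}

#' Build a group-level mask by subject-frequency thresholding
#'
#' The per-voxel frequency map is the mean of the subjects' binary masks; a
#' voxel enters the group mask when its frequency is greater than or equal to
#' the threshold (a voxel present in exactly 95% of subjects is kept at
#' threshold 0.95).
#'
#' @param masks list of `binary_mask` objects on one grid.
#' @param threshold frequency threshold in (0, 1].
#' @return An object of class `group_mask`: fields `mask` (a `binary_mask`),
#'   `frequency` (numeric array) and `threshold`.
#' @export
build_group_mask <- function(masks, threshold = 0.95) {
  if (length(masks) < 1L) stop("build_group_mask: need at least one mask")
  grid <- masks[[1]]$grid
  for (m in masks) {
    stopifnot(inherits(m, "binary_mask"))
    if (!grids_equal(grid, m$grid))
      stop("build_group_mask: grid mismatch across masks")
  }
  freq <- Reduce(`+`, lapply(masks, function(m) m$data + 0)) / length(masks)
  keep <- freq >= threshold
  if (!any(keep))
    stop("build_group_mask: no voxel reaches threshold ", threshold)
  structure(list(mask = binary_mask(keep, grid, masks[[1]]$tissue),
                 frequency = freq, threshold = threshold),
            class = "group_mask")
}

#' Restrict an atlas to a group mask
#'
#' Labels outside the mask are set to background (0). Any label wholly lost
#' by the restriction is an error naming the label, so a bundle can never
#' silently vanish; surviving per-label voxel counts are returned as the
#' `counts` attribute.
#'
#' @param atlas a `labeled_volume` of integer labels (0 = background).
#' @param group_mask a `group_mask` (or `binary_mask`) on the same grid.
#' @return The restricted `labeled_volume` with a `counts` attribute
#'   (named vector of surviving voxel counts per label).
#' @export
restrict_atlas <- function(atlas, group_mask) {
  mask <- if (inherits(group_mask, "group_mask")) group_mask$mask else
    group_mask
  if (!grids_equal(atlas$grid, mask$grid))
    stop("restrict_atlas: atlas and mask grids differ")
  lab <- atlas$data
  before <- sort(unique(lab[lab != 0L]))
  lab[!mask$data] <- 0L
  after <- table(lab[lab != 0L])
  lost <- setdiff(before, as.integer(names(after)))
  if (length(lost))
    stop("restrict_atlas: label(s) left with 0 voxels after masking: ",
         paste(lost, collapse = ", "))
  out <- labeled_volume(lab, atlas$grid)
  counts <- as.integer(after)
  names(counts) <- names(after)
  attr(out, "counts") <- counts
  out
}

#' Regress confounds out of a BOLD run
#'
#' Replaces every voxel series by its least-squares residual against an
#' intercept plus the confound columns (e.g. head-motion parameters and the
#' CSF mean signal). With no confounds this removes the temporal mean only.
#'
#' @param run a `bold_run`.
#' @param confounds time x regressor numeric matrix, or `NULL`.
#' @return A `bold_run` of residual series.
#' @export
regress_confounds <- function(run, confounds = NULL) {
  stopifnot(inherits(run, "bold_run"))
  tt <- dim(run$data)[4]
  x <- matrix(1, tt, 1L)
  if (!is.null(confounds) && NCOL(confounds) > 0L) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != tt)
      stop("regress_confounds: confound rows (", nrow(confounds),
           ") do not match time extent (", tt, ")")
    x <- cbind(x, confounds)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x))
    stop("regress_confounds: rank-deficient design matrix")
  nvox <- prod(dim(run$data)[1:3])
  y <- t(matrix(run$data, nvox, tt))            # time x voxel
  res <- qr.resid(qx, y)
  out <- array(t(res), dim = dim(run$data))
  bold_run(out, run$grid, run$tr, run$subject_id)
}

# Zero-phase frequency-domain bandpass of the columns of a T x V matrix,
# after per-column linear detrend. DC and out-of-band bins are zeroed; the
# mask is real, so no temporal shift is introduced.
fft_bandpass <- function(x, tr, low, high) {
  x <- as.matrix(x)
  tt <- nrow(x)
  tim <- seq_len(tt)
  d <- cbind(1, tim)
  x <- qr.resid(qr(d), x)                       # linear detrend
  k <- 0:(tt - 1)
  freq <- pmin(k, tt - k) / (tt * tr)
  keep <- freq >= low & freq <= high
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / tt
}

#' Temporal bandpass filter
#'
#' Zero-phase frequency-domain filter: each voxel series is linearly
#' detrended, transformed with the FFT, bins with frequency outside
#' `[low, high]` are zeroed, and the series is transformed back. A sinusoid
#' inside the band is passed essentially unchanged (no phase shift); DC and
#' out-of-band components are removed.
#'
#' @param run a `bold_run`.
#' @param low,high passband edges in Hz; require `0 <= low < high < 1/(2 tr)`.
#' @return The filtered `bold_run`.
#' @export
bandpass_filter <- function(run, low = 0.01, high = 0.1) {
  stopifnot(inherits(run, "bold_run"))
  nyq <- 1 / (2 * run$tr)
  if (!(low >= 0 && low < high && high < nyq))
    stop("bandpass_filter: band [", low, ", ", high,
         "] invalid for TR ", run$tr, " (Nyquist ", signif(nyq, 4), " Hz)")
  tt <- dim(run$data)[4]
  nvox <- prod(dim(run$data)[1:3])
  y <- t(matrix(run$data, nvox, tt))
  out <- array(t(fft_bandpass(y, run$tr, low, high)), dim = dim(run$data))
  bold_run(out, run$grid, run$tr, run$subject_id)
}

# 1-D Gaussian convolution matrix with truncated, renormalized kernel:
# every row sums to 1, so constants are preserved up to the boundary.
gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  offs <- -r:r
  g <- exp(-offs^2 / (2 * sigma^2))
  k <- matrix(0, n, n)
  for (a in seq_len(n)) {
    b <- a + offs
    ok <- b >= 1 & b <= n
    k[a, b[ok]] <- g[ok] / sum(g[ok])
  }
  k
}

#' Spatial Gaussian smoothing
#'
#' Separable 3-D Gaussian smoothing of each time frame, with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis converted to voxel units. The
#' kernel is truncated at 3 sigma and renormalized, so uniform volumes are
#' preserved exactly including at the boundary. `fwhm = 0` is the identity.
#'
#' @param run a `bold_run`.
#' @param fwhm kernel full width at half maximum in mm (>= 0).
#' @return The smoothed `bold_run`.
#' @export
spatial_smooth <- function(run, fwhm) {
  stopifnot(inherits(run, "bold_run"))
  if (fwhm < 0) stop("spatial_smooth: fwhm must be >= 0")
  if (fwhm == 0) return(run)
  sh <- dim(run$data)[1:3]
  tt <- dim(run$data)[4]
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  ks <- lapply(1:3, function(a) gauss_conv_matrix(sh[a],
                                                  sigma_mm /
                                                    run$grid$voxel_size[a]))
  out <- run$data
  for (t in seq_len(tt)) {
    v <- out[, , , t]
    v <- array(ks[[1]] %*% matrix(v, sh[1]), dim = sh)
    v <- aperm(array(ks[[2]] %*% matrix(aperm(v, c(2, 1, 3)), sh[2]),
                     dim = sh[c(2, 1, 3)]), c(2, 1, 3))
    v <- aperm(array(ks[[3]] %*% matrix(aperm(v, c(3, 1, 2)), sh[3]),
                     dim = sh[c(3, 1, 2)]), c(2, 3, 1))
    out[, , , t] <- v
  }
  bold_run(out, run$grid, run$tr, run$subject_id)
}

#' Run the per-subject preprocessing chain
#'
#' Applies, in order, confound regression, temporal bandpass and spatial
#' smoothing (the order of the last two can be swapped via
#' `smooth_before_filter`).
#'
#' @param run a `bold_run`.
#' @param config a [run_config()].
#' @param confounds time x regressor matrix or `NULL`. Columns with (near)
#'   zero variance are dropped with a message rather than making the design
#'   rank-deficient.
#' @return The preprocessed `bold_run`.
#' @export
preprocess_run <- function(run, config, confounds = NULL) {
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    sds <- apply(confounds, 2, stats::sd)
    drop <- !is.finite(sds) | sds < 1e-12
    if (any(drop)) {
      message("preprocess_run: dropping ", sum(drop),
              " zero-variance confound column(s)")
      confounds <- confounds[, !drop, drop = FALSE]
    }
    if (ncol(confounds) == 0L) confounds <- NULL
  }
  run <- regress_confounds(run, confounds)
  if (isTRUE(config$smooth_before_filter)) {
    run <- spatial_smooth(run, config$fwhm)
    run <- bandpass_filter(run, config$band[1], config$band[2])
  } else {
    run <- bandpass_filter(run, config$band[1], config$band[2])
    run <- spatial_smooth(run, config$fwhm)
  }
  run
}
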