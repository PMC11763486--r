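# Corpus-callosum sub-analyses: gradient distributions over genu/body/
# splenium, extreme-group construction on the first gradient, and
# correlations of extreme-voxel group-averaged BOLD against parcel series.

#' Corpus-callosum subregion parcellation
#'
#' Extracts the genu/body/splenium sublabels of a (mask-restricted) atlas as
#' a voxel table. Each masked CC voxel belongs to exactly one sublabel; every
#' sublabel must be non-empty.
#'
#' @param atlas restricted `labeled_volume` containing the CC label codes
#'   (genu 101, body 102, splenium 103 in the synthetic atlas).
#' @param cc_codes named integer vector of sublabel codes.
#' @return A `cc_parcellation` data frame with 0-based `i, j, k` and
#'   `sublabel` in `{genu, body, splenium}`.
#' @export
cc_parcellation <- function(atlas, cc_codes = CC_LABELS) {
  lab <- atlas$data
  rows <- lapply(seq_along(cc_codes), function(t) {
    idx <- which(lab == cc_codes[t], arr.ind = TRUE)
    if (nrow(idx) == 0L)
      stop("cc_parcellation: empty sublabel ", names(cc_codes)[t])
    idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE] - 1L
    data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
               sublabel = sub("^cc_", "", names(cc_codes)[t]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cc_parcellation", "data.frame")
  out
}

# rows of `parcel` located in the gradient set's voxel order; errors if a CC
# voxel is missing from the embedding
.match_cc_rows <- function(template, parcel) {
  vi <- template$voxel_index
  if (is.null(vi)) stop("gradient set carries no voxel index")
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  pos <- match(key(as.matrix(parcel[, c("i", "j", "k")])), key(vi))
  if (anyNA(pos))
    stop(sum(is.na(pos)), " CC voxel(s) not present in the gradient set")
  pos
}

#' Gradient-value distributions over CC subregions
#'
#' Collects the chosen component's values over each of genu, body and
#' splenium and summarizes them (quartiles and a shared-break histogram).
#' Every masked CC voxel contributes to exactly one collection.
#'
#' @param template a `gradient_set` (typically the group template).
#' @param parcel a [cc_parcellation()].
#' @param component which gradient to map (2 and 3 are the ones examined for
#'   the CC).
#' @param breaks number of histogram bins.
#' @return A list with `values` (named list of numeric vectors per sublabel),
#'   `summary` (data frame of n, quartiles, mean) and `histogram` (counts per
#'   sublabel on shared breaks).
#' @export
cc_distribution <- function(template, parcel, component = 2L, breaks = 10L) {
  if (component < 1L || component > ncol(template$components))
    stop("cc_distribution: component ", component, " not available")
  pos <- .match_cc_rows(template, parcel)
  v <- template$components[pos, component]
  values <- split(v, parcel$sublabel)
  sm <- do.call(rbind, lapply(names(values), function(s) {
    q <- stats::quantile(values[[s]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(sublabel = s, n = length(values[[s]]),
               q25 = q[1], median = q[2], q75 = q[3],
               mean = mean(values[[s]]), stringsAsFactors = FALSE)
  }))
  brk <- if (diff(range(v)) < 1e-12)
    c(v[1] - 1e-9, v[1] + 1e-9)
  else
    seq(min(v), max(v), length.out = breaks + 1L)
  brk[1] <- brk[1] - 1e-9; brk[length(brk)] <- brk[length(brk)] + 1e-9
  hist <- sapply(values, function(x)
    as.integer(table(cut(x, brk, include.lowest = TRUE))))
  list(values = values, summary = sm, histogram = hist, breaks = brk,
       component = component)
}

#' Extreme max/min voxel groups on a CC gradient
#'
#' Finds the `k` largest-valued and `k` smallest-valued CC voxels on the
#' chosen component (the published analysis uses the first gradient and
#' k = 30). Ties at the k-th order statistic are broken by canonical voxel
#' order, so the groups are deterministic; they are disjoint and every value
#' in the max group is >= every value in the min group.
#'
#' @param template a `gradient_set`.
#' @param parcel a [cc_parcellation()].
#' @param component gradient component (default 1).
#' @param k group size; requires `2k <=` number of CC voxels.
#' @return An `extreme_groups` list: `max_voxels` / `min_voxels` (data frames
#'   with voxel indices, sublabel and value, ordered from most extreme),
#'   `component`, `k`.
#' @export
extreme_groups <- function(template, parcel, component = 1L, k = 30L) {
  n <- nrow(parcel)
  if (2L * k > n)
    stop("extreme_groups: 2k = ", 2L * k, " exceeds CC size ", n)
  pos <- .match_cc_rows(template, parcel)
  v <- template$components[pos, component]
  ord_max <- order(-v, seq_len(n))
  ord_min <- order(v, seq_len(n))
  take <- function(ord) {
    sel <- ord[seq_len(k)]
    out <- parcel[sel, , drop = FALSE]
    out$value <- v[sel]
    out$row <- pos[sel]          # row in the gradient set's voxel order
    rownames(out) <- NULL
    out
  }
  structure(list(max_voxels = take(ord_max), min_voxels = take(ord_min),
                 component = component, k = as.integer(k)),
            class = "extreme_groups")
}

#' Group-averaged BOLD series at selected voxels
#'
#' Averages the subjects' preprocessed BOLD series voxel-wise: entry (v, t)
#' is the mean over subjects at voxel v, time t. All runs must share the
#' grid and time extent.
#'
#' @param runs list of `bold_run` objects.
#' @param voxels n x 3 matrix of 0-based voxel indices (or a data frame with
#'   columns `i, j, k`).
#' @return n x time numeric matrix with a `voxel_index` attribute.
#' @export
group_average_bold <- function(runs, voxels) {
  stopifnot(length(runs) >= 1L)
  if (is.data.frame(voxels)) voxels <- as.matrix(voxels[, c("i", "j", "k")])
  voxels <- matrix(as.integer(voxels), ncol = 3L)
  grid <- runs[[1]]$grid
  tt <- dim(runs[[1]]$data)[4]
  sh <- grid$shape
  if (any(voxels < 0L) || any(voxels >= matrix(sh, nrow(voxels), 3,
                                               byrow = TRUE)))
    stop("group_average_bold: voxel index outside the grid")
  lin <- voxels[, 1] + 1L + sh[1] * (voxels[, 2] + sh[2] * voxels[, 3])
  acc <- matrix(0, nrow(voxels), tt)
  for (run in runs) {
    if (!grids_equal(run$grid, grid))
      stop("group_average_bold: grid mismatch across subjects")
    if (dim(run$data)[4] != tt)
      stop("group_average_bold: unequal run lengths (", tt, " vs ",
           dim(run$data)[4], ")")
    acc <- acc + matrix(run$data, prod(sh), tt)[lin, , drop = FALSE]
  }
  structure(acc / length(runs), voxel_index = voxels)
}

#' Parcel-mean time series
#'
#' Averages a voxel x time matrix over the voxels of each parcel of a
#' labelled volume. Every requested parcel must have at least one voxel
#' among the supplied rows.
#'
#' @param bold voxel x time matrix with a `voxel_index` attribute (e.g. from
#'   [group_average_bold()]).
#' @param parcellation a `labeled_volume`; label 0 is background.
#' @param parcel_names optional named character vector mapping label codes to
#'   names.
#' @return parcel x time matrix with parcel names as row names.
#' @export
parcel_mean_timeseries <- function(bold, parcellation, parcel_names = NULL) {
  vi <- attr(bold, "voxel_index")
  if (is.null(vi)) stop("parcel_mean_timeseries: bold has no voxel_index")
  codes <- parcellation$data[vi + 1L]
  labels <- sort(unique(parcellation$data[parcellation$data != 0L]))
  out <- matrix(NA_real_, length(labels), ncol(bold))
  for (li in seq_along(labels)) {
    rows <- which(codes == labels[li])
    if (length(rows) == 0L)
      stop("parcel_mean_timeseries: empty parcel ",
           label_to_name(labels[li], parcel_names))
    out[li, ] <- colMeans(bold[rows, , drop = FALSE])
  }
  rownames(out) <- label_to_name(labels, parcel_names)
  out
}

#' Correlate extreme-group voxel series with parcel series
#'
#' For each of the max and min groups, entry (v, r) is the Pearson
#' correlation between extreme voxel v's group-averaged series and parcel
#' r's mean series — the published analysis reports the resulting 30 x 82
#' (GM) and 30 x 48 (WM) matrices per group.
#'
#' @param groups an [extreme_groups()] object.
#' @param group_bold voxel x time matrix over the CC voxels (rows matching
#'   the `voxel_index` attribute) from [group_average_bold()].
#' @param parcel_ts parcel x time matrix from [parcel_mean_timeseries()].
#' @return A list with `max` and `min`: k x R correlation matrices with
#'   parcel names as column names.
#' @export
extreme_region_correlation <- function(groups, group_bold, parcel_ts) {
  if (ncol(group_bold) != ncol(parcel_ts))
    stop("extreme_region_correlation: time extents differ")
  vi <- attr(group_bold, "voxel_index")
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  corr_for <- function(vox) {
    rows <- match(key(as.matrix(vox[, c("i", "j", "k")])), key(vi))
    if (anyNA(rows))
      stop("extreme_region_correlation: extreme voxel missing from bold")
    x <- group_bold[rows, , drop = FALSE]
    sx <- apply(x, 1, stats::sd)
    sp <- apply(parcel_ts, 1, stats::sd)
    if (any(sx == 0) || any(sp == 0))
      stop("extreme_region_correlation: zero-variance series")
    r <- stats::cor(t(x), t(parcel_ts))
    r <- pmin(pmax(r, -1), 1)
    colnames(r) <- rownames(parcel_ts)
    r
  }
  list(max = corr_for(groups$max_voxels), min = corr_for(groups$min_voxels))
}

#' Compare max- and min-group correlation profiles per parcel
#'
#' For each parcel: the mean correlation of each extreme group across its k
#' voxels, their difference, and a flag for parcels where the minimum group
#' exceeds the maximum group (the exception cases).
#'
#' @param max_mat,min_mat k x R correlation matrices over the same parcels.
#' @return Data frame with `parcel`, `mean_max`, `mean_min`, `difference`,
#'   `min_gt_max`.
#' @export
compare_groups <- function(max_mat, min_mat) {
  if (!identical(colnames(max_mat), colnames(min_mat)) ||
      ncol(max_mat) != ncol(min_mat))
    stop("compare_groups: parcel sets differ")
  mmax <- colMeans(max_mat)
  mmin <- colMeans(min_mat)
  data.frame(parcel = colnames(max_mat), mean_max = mmax, mean_min = mmin,
             difference = mmax - mmin, min_gt_max = mmin > mmax,
             row.names = NULL, stringsAsFactors = FALSE)
}
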