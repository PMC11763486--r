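# Synthetic cohort generator.
#
# Builds a toy brain on a small grid: a CSF border, a one-voxel gray-matter
# shell, a white-matter core split into >= 4 left/right bundle pairs, and a
# midline corpus-callosum slab partitioned into genu/body/splenium along the
# anterior-posterior (j) axis. Every white-matter voxel carries a latent
# gradient coordinate (`axis_value`, its normalized j position); its BOLD
# series is a Gaussian-bump mixture of band-limited network time courses
# whose weights vary smoothly with that coordinate, so the first diffusion
# gradient of the WM-GM connectome should recover the planted axis. A
# left-hemisphere shift of `axis_value` in designated bundles plants a
# detectable asymmetry.

#' Parameters of the synthetic cohort
#'
#' Defaults describe the stated world the test-suite exercises: a 12x14x12
#' grid at 2 mm (roughly 560 white-matter and 320 gray-matter voxels),
#' 3 subjects per group, 200 timepoints at TR = 0.72 s, 20 gray-matter
#' network sources spaced along the latent axis, noise at half the signal
#' SD, a 0.02 axis shift planted in the left half of `bundle1` (the planted
#' asymmetry is a perturbation of the latent manifold, not a
#' reorganization), and 10% ambiguous boundary voxels.
#'
#' @param grid_shape 3 integer extents (first extent must be even so the
#'   midline falls between voxel columns).
#' @param n_per_group subjects per group (groups are labelled M and F).
#' @param n_timepoints number of BOLD frames (>= 8).
#' @param tr repetition time in seconds.
#' @param n_networks number of gray-matter network time courses (>= 2).
#' @param noise_sd SD of iid Gaussian voxel noise; network signals have SD 1.
#' @param asym_effect shift added to `axis_value` in left-hemisphere voxels of
#'   `asym_bundles` for group M (and for group F unless `asym_effect_f` set).
#' @param asym_effect_f optional distinct shift for group F.
#' @param asym_bundles names of bundles carrying the planted asymmetry.
#' @param ambiguous_frac fraction of WM/GM boundary voxels whose tissue class
#'   flips across subjects (in [0, 0.5)).
#' @param seed master seed; per-subject seeds are derived from it.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(grid_shape = c(12L, 14L, 12L),
                             n_per_group = 3L,
                             n_timepoints = 200L,
                             tr = 0.72,
                             n_networks = 20L,
                             noise_sd = 0.5,
                             asym_effect = 0.02,
                             asym_effect_f = NULL,
                             asym_bundles = "bundle1",
                             ambiguous_frac = 0.1,
                             seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  if (grid_shape[1] %% 2L != 0L)
    stop("synthetic_params: first grid extent must be even")
  if (n_timepoints < 8L) stop("synthetic_params: n_timepoints must be >= 8")
  if (n_networks < 2L) stop("synthetic_params: n_networks must be >= 2")
  if (!(ambiguous_frac >= 0 && ambiguous_frac < 0.5))
    stop("synthetic_params: ambiguous_frac must be in [0, 0.5)")
  if (noise_sd < 0) stop("synthetic_params: noise_sd must be >= 0")
  if (n_per_group < 1L) stop("synthetic_params: n_per_group must be >= 1")
  structure(list(grid_shape = grid_shape,
                 n_per_group = as.integer(n_per_group),
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 n_networks = as.integer(n_networks), noise_sd = noise_sd,
                 asym_effect = asym_effect, asym_effect_f = asym_effect_f,
                 asym_bundles = as.character(asym_bundles),
                 ambiguous_frac = ambiguous_frac, seed = as.integer(seed)),
            class = "synthetic_params")
}

# label codes used in the synthetic atlas
CC_LABELS <- c(cc_genu = 101L, cc_body = 102L, cc_splenium = 103L)

#' Hemisphere of voxels by world x coordinate
#'
#' Left/right membership is defined in world coordinates after applying the
#' grid affine, not by array index: `L` where x < -tol, `R` where x > tol,
#' `midline` within one voxel of x = 0.
#'
#' @param grid a [volume_grid()].
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @return Character vector in `{"L", "R", "midline"}`.
#' @export
hemisphere_of <- function(grid, ijk) {
  x <- voxel_to_world(grid, ijk)[, 1]
  tol <- grid$voxel_size[1] * 0.999
  ifelse(x < -tol, "L", ifelse(x > tol, "R", "midline"))
}

#' Build the synthetic geometry and ground truth
#'
#' Constructs the tissue-probability maps, the white-matter bundle atlas with
#' corpus-callosum sublabels, the gray-matter parcellation, and the planted
#' ground truth (per-voxel axis value and network mixing weights). Tissue
#' probabilities sum to 1 per voxel; a deterministic subset of WM/GM boundary
#' voxels is marked ambiguous so the group-mask thresholding has work to do.
#'
#' @param params a [synthetic_params()].
#' @return A list with `grid`, `tissue` (list of wm/gm/csf probability
#'   arrays), `atlas` (a `labeled_volume`; bundles 1..4, CC sublabels
#'   101..103), `gm_parcels` (a `labeled_volume`), `truth` (data frame with
#'   0-based `i, j, k`, `axis_value`, `bundle`, `hemisphere`, `cc_sublabel`),
#'   `mixing` (WM voxel x network weights), `bundle_names`, `ambiguous`
#'   (0-based index matrix of ambiguous voxels) and `gm_networks` (network id
#'   per GM voxel, in atlas voxel order).
#' @export
make_geometry <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  sh <- params$grid_shape
  nx <- sh[1]; ny <- sh[2]; nz <- sh[3]
  if (nx < 10L || ny < 8L || nz < 8L)
    stop("make_geometry: grid too small to host GM shell, bundles and CC")
  grid <- volume_grid(sh, voxel_size = c(2, 2, 2))

  # 0-based index ranges of the compartments
  wm_i <- 2:(nx - 3); wm_j <- 2:(ny - 3); wm_k <- 2:(nz - 3)
  mid_i <- c(nx / 2 - 1, nx / 2)
  left_i <- wm_i[wm_i < min(mid_i)]
  right_i <- wm_i[wm_i > max(mid_i)]
  kc0 <- max(min(wm_k), floor((min(wm_k) + max(wm_k)) / 2) - 1)
  cc_k <- intersect(kc0:(kc0 + 3), wm_k)
  if (length(left_i) < 1L || length(right_i) < 1L || length(cc_k) < 1L)
    stop("make_geometry: grid too small to host GM shell, bundles and CC")

  lab <- array(0L, dim = sh)          # atlas labels, 1-based array indexing
  tis <- array("csf", dim = sh)       # tissue class per voxel
  at <- function(i, j, k) cbind(i + 1L, j + 1L, k + 1L)

  # gray-matter shell: one-voxel ring around the WM core, same k range
  ring <- expand.grid(i = 1:(nx - 2), j = 1:(ny - 2))
  ring <- ring[ring$i %in% c(1, nx - 2) | ring$j %in% c(1, ny - 2), ]
  for (k in wm_k) tis[at(ring$i, ring$j, k)] <- "gm"

  # paired bundles: left/right blocks split into j and k halves
  j_half <- split(wm_j, wm_j > stats::median(wm_j))
  k_half <- split(wm_k, wm_k > stats::median(wm_k))
  bundle_names <- paste0("bundle", 1:4)
  b <- 0L
  for (jh in j_half) for (kh in k_half) {
    b <- b + 1L
    blk <- expand.grid(i = c(left_i, right_i), j = jh, k = kh)
    lab[at(blk$i, blk$j, blk$k)] <- b
    tis[at(blk$i, blk$j, blk$k)] <- "wm"
  }

  # corpus callosum: midline slab, genu/body/splenium by j thirds
  thirds <- cut(wm_j, 3, labels = FALSE)
  cc_codes <- unname(CC_LABELS)
  for (t in 1:3) {
    blk <- expand.grid(i = mid_i, j = wm_j[thirds == t], k = cc_k)
    lab[at(blk$i, blk$j, blk$k)] <- cc_codes[t]
    tis[at(blk$i, blk$j, blk$k)] <- "wm"
  }
  if (any(vapply(cc_codes, function(cc) sum(lab == cc), 0L) < 1L))
    stop("make_geometry: grid too small to host CC sublabels")

  # base tissue probabilities: dominant class 0.9, others 0.05
  p_wm <- array(0.05, dim = sh); p_gm <- array(0.05, dim = sh)
  p_csf <- array(0.05, dim = sh)
  p_wm[tis == "wm"] <- 0.9
  p_gm[tis == "gm"] <- 0.9
  p_csf[tis == "csf"] <- 0.9

  # ambiguous boundary voxels: WM voxels on the core's outer face
  wm_idx0 <- which(tis == "wm", arr.ind = TRUE) - 1L
  boundary <- wm_idx0[wm_idx0[, 1] %in% range(wm_i) |
                        wm_idx0[, 2] %in% range(wm_j), , drop = FALSE]
  n_amb <- floor(params$ambiguous_frac * nrow(boundary))
  ambiguous <- boundary[seq_len(0), , drop = FALSE]
  if (n_amb > 0L) {
    ord <- order(boundary[, 1], boundary[, 2], boundary[, 3])
    pick <- with_seed(derive_seed(params$seed, 0L), sample(ord, n_amb))
    ambiguous <- boundary[pick, , drop = FALSE]
    ai <- ambiguous + 1L
    p_wm[ai] <- 0.48; p_gm[ai] <- 0.47; p_csf[ai] <- 0.05
  }

  # ground truth: latent gradient coordinate. The raw coordinate runs along
  # the anterior-posterior (j) axis with smaller mirror-symmetric
  # contributions from k and from distance to the midline, so values vary
  # continuously in 3-D while remaining monotone in j and identical across
  # L/R mirror pairs; the rank transform makes the sampling density uniform
  # on [0, 1], which keeps the leading diffusion mode global rather than
  # localized where voxels are dense.
  wm_idx0 <- wm_idx0[order(wm_idx0[, 1], wm_idx0[, 2], wm_idx0[, 3]), ,
                     drop = FALSE]
  axis <- rank_uniform(raw_axis_coord(grid, wm_idx0))
  codes <- lab[wm_idx0 + 1L]
  bundle <- ifelse(codes %in% cc_codes,
                   names(CC_LABELS)[match(codes, cc_codes)],
                   bundle_names[codes])
  hemi <- hemisphere_of(grid, wm_idx0)
  hemi[codes %in% cc_codes] <- "midline"
  ccsub <- ifelse(codes %in% cc_codes,
                  sub("^cc_", "", names(CC_LABELS)[match(codes, cc_codes)]),
                  NA_character_)
  truth <- data.frame(i = wm_idx0[, 1], j = wm_idx0[, 2], k = wm_idx0[, 3],
                      axis_value = axis, bundle = bundle, hemisphere = hemi,
                      cc_sublabel = ccsub, stringsAsFactors = FALSE)

  # gray-matter parcellation (hemisphere x j-quartile -> 8 parcels) and
  # network assignment by anterior-posterior position
  gm_idx0 <- which(tis == "gm", arr.ind = TRUE) - 1L
  gm_idx0 <- gm_idx0[order(gm_idx0[, 1], gm_idx0[, 2], gm_idx0[, 3]), ,
                     drop = FALSE]
  gm_axis <- rank_uniform(raw_axis_coord(grid, gm_idx0))
  centers <- (seq_len(params$n_networks) - 0.5) / params$n_networks
  gm_net <- apply(abs(outer(gm_axis, centers, "-")), 1, which.min)
  gm_x <- voxel_to_world(grid, gm_idx0)[, 1]
  jq <- pmin(1L + floor(gm_axis * 4), 4L)
  parc <- array(0L, dim = sh)
  parc[gm_idx0 + 1L] <- ifelse(gm_x < 0, jq, jq + 4L)

  geom <- list(grid = grid,
               tissue = list(wm = p_wm, gm = p_gm, csf = p_csf),
               atlas = labeled_volume(lab, grid),
               gm_parcels = labeled_volume(parc, grid),
               truth = truth,
               bundle_names = c(bundle_names, names(CC_LABELS)),
               ambiguous = ambiguous,
               gm_voxels = gm_idx0,
               gm_networks = gm_net,
               centers = centers)
  geom$mixing <- mixing_weights(truth$axis_value, centers)
  geom
}

# Raw latent coordinate of voxels: dominated by the anterior-posterior (j)
# position with smaller contributions from k and distance to the midline.
# Mirror-symmetric in x so L/R voxel pairs share a value.
raw_axis_coord <- function(grid, idx0) {
  idx0 <- matrix(idx0, ncol = 3L)
  m <- abs(voxel_to_world(grid, idx0)[, 1])
  nrm <- function(v) if (diff(range(v)) == 0) rep(0, length(v)) else
    (v - min(v)) / diff(range(v))
  nrm(idx0[, 2]) + 0.4 * nrm(idx0[, 3]) + 0.2 * nrm(m)
}

# map values to a uniform grid on [0, 1] preserving order (average ties)
rank_uniform <- function(v) {
  (rank(v, ties.method = "average") - 1) / (length(v) - 1)
}

# Gaussian-bump soft assignment of axis values over network centers;
# rows are non-negative and sum to 1.
mixing_weights <- function(axis_value, centers, bump_sd = 0.15) {
  w <- exp(-outer(axis_value, centers, "-")^2 / (2 * bump_sd^2))
  w / rowSums(w)
}

# Apply the planted left-hemisphere axis shift for one subject's group and
# return the per-voxel axis values (the subject-level ground truth).
subject_axis <- function(geom, params, group = "M") {
  axis <- geom$truth$axis_value
  eff <- params$asym_effect
  if (group == "F" && !is.null(params$asym_effect_f))
    eff <- params$asym_effect_f
  shift <- geom$truth$hemisphere == "L" &
    geom$truth$bundle %in% params$asym_bundles
  axis[shift] <- axis[shift] + eff
  axis
}

# Band-limited network time courses (T x M): white noise filtered to the
# band, then orthonormalized (QR stays inside the band's Fourier span) and
# scaled to zero mean, unit sample SD. Exact empirical orthogonality makes
# the networks "well separated": the noise-free voxel correlations are an
# exact function of the mixing weights. The band must carry at least M
# Fourier degrees of freedom.
network_timecourses <- function(n_timepoints, n_networks, tr, band) {
  k <- 0:(n_timepoints - 1)
  freq <- pmin(k, n_timepoints - k) / (n_timepoints * tr)
  band_dim <- sum(freq >= band[1] & freq <= band[2])
  if (band_dim < n_networks)
    stop("network_timecourses: band carries only ", band_dim,
         " degrees of freedom for ", n_networks,
         " networks; increase n_timepoints or reduce n_networks")
  x <- matrix(stats::rnorm(n_timepoints * n_networks), n_timepoints)
  # alternating projections onto (band-limited) ∩ (linear-trend-free):
  # the resulting courses are an exact fixed point of the detrend+bandpass
  # filter, so preprocessing leaves the planted signal untouched
  for (it in 1:80) x <- fft_bandpass(x, tr, band[1], band[2])
  q <- qr.Q(qr(x))
  q * sqrt(n_timepoints - 1)
}

#' Simulate one subject's BOLD run
#'
#' Gray-matter voxels receive their assigned network time course plus iid
#' Gaussian noise; white-matter voxels receive the mixing-weighted sum of all
#' network time courses, rescaled to unit SD so `noise_sd` is expressed as a
#' fraction of the signal SD everywhere (weights a Gaussian-bump function of
#' the voxel's planted axis value, shifted by the asymmetry effect in
#' left-hemisphere voxels of the designated bundles); CSF and background voxels
#' are pure noise. Network time courses are white noise filtered to the
#' 0.01-0.1 Hz band so downstream temporal filtering preserves them.
#'
#' @param geom geometry from [make_geometry()].
#' @param params a [synthetic_params()].
#' @param subject_seed integer seed for this subject (required; the generator
#'   never touches the global RNG state implicitly).
#' @param group group label, `"M"` or `"F"`.
#' @param subject_id identifier stored in the run.
#' @return A `bold_run`; attribute `networks` holds the realized T x M
#'   network time-course matrix and attribute `axis_value` the subject-level
#'   shifted axis values (WM voxels in `geom$truth` row order).
#' @export
simulate_subject <- function(geom, params, subject_seed, group = "M",
                             subject_id = "sub") {
  if (missing(subject_seed) || is.null(subject_seed))
    stop("simulate_subject: subject_seed is required")
  sh <- params$grid_shape
  tt <- params$n_timepoints
  axis <- subject_axis(geom, params, group)
  w <- mixing_weights(axis, geom$centers)
  dat <- with_seed(subject_seed, {
    s <- network_timecourses(tt, params$n_networks, params$tr, c(0.01, 0.1))
    arr <- array(stats::rnorm(prod(sh) * tt, sd = params$noise_sd),
                 dim = c(sh, tt))
    wm_lin <- geom$truth$i + 1L + sh[1] * (geom$truth$j + sh[2] * geom$truth$k)
    gm_lin <- geom$gm_voxels[, 1] + 1L +
      sh[1] * (geom$gm_voxels[, 2] + sh[2] * geom$gm_voxels[, 3])
    nvol <- prod(sh)
    wm_sig <- tcrossprod(w, s) / sqrt(rowSums(w^2)) # WM voxel x time, unit SD
    gm_sig <- t(s[, geom$gm_networks, drop = FALSE])
    for (t in seq_len(tt)) {
      off <- (t - 1L) * nvol
      arr[off + wm_lin] <- arr[off + wm_lin] + wm_sig[, t]
      arr[off + gm_lin] <- arr[off + gm_lin] + gm_sig[, t]
    }
    list(arr = arr, s = s)
  })
  run <- bold_run(dat$arr, geom$grid, tr = params$tr, subject_id = subject_id)
  attr(run, "networks") <- dat$s
  attr(run, "axis_value") <- axis
  run
}

#' Simulate and write a full cohort
#'
#' Writes `2 * n_per_group` subjects (groups M then F) under `outdir`:
#' per-subject BOLD and tissue-probability NIfTI volumes (tissue classes of
#' ambiguous boundary voxels flip at random across subjects), the atlas and
#' gray-matter parcellation, a `manifest.csv`, and a `ground_truth.tsv`
#' sidecar with per-voxel axis values, bundle, hemisphere and CC sublabel.
#' Per-subject seeds are derived deterministically from `params$seed`.
#'
#' @param params a [synthetic_params()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the `cohort_manifest`, the geometry and the
#'   paths of the atlas/parcellation volumes.
#' @export
simulate_cohort <- function(params, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("simulate_cohort: cannot create output directory ", outdir)
  geom <- make_geometry(params)
  n <- 2L * params$n_per_group
  groups <- rep(c("M", "F"), each = params$n_per_group)
  ids <- sprintf("sub%03d", seq_len(n))
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    seed_s <- derive_seed(params$seed, s)
    run <- simulate_subject(geom, params, subject_seed = seed_s,
                            group = groups[s], subject_id = ids[s])
    bold_path <- file.path(outdir, paste0(ids[s], "_bold.nii.gz"))
    write_nifti(run$data, bold_path, geom$grid, tr = params$tr)
    tp <- geom$tissue
    if (nrow(geom$ambiguous) > 0L) {
      flip <- with_seed(derive_seed(params$seed, 100000L + s),
                        stats::runif(nrow(geom$ambiguous)) < 0.5)
      ai <- geom$ambiguous[flip, , drop = FALSE] + 1L
      tmp <- tp$wm[ai]; tp$wm[ai] <- tp$gm[ai]; tp$gm[ai] <- tmp
    }
    tpaths <- file.path(outdir, paste0(ids[s], "_", c("wm", "gm", "csf"),
                                       "_prob.nii.gz"))
    write_nifti(tp$wm, tpaths[1], geom$grid)
    write_nifti(tp$gm, tpaths[2], geom$grid)
    write_nifti(tp$csf, tpaths[3], geom$grid)
    rows[[s]] <- data.frame(subject_id = ids[s],
                            bold_path = basename(bold_path),
                            wm_prob_path = basename(tpaths[1]),
                            gm_prob_path = basename(tpaths[2]),
                            csf_prob_path = basename(tpaths[3]),
                            group = groups[s], tr = params$tr,
                            stringsAsFactors = FALSE)
  }
  manifest_df <- do.call(rbind, rows)
  manifest_path <- file.path(outdir, "manifest.csv")
  utils::write.csv(manifest_df, manifest_path, row.names = FALSE)
  write_nifti(geom$atlas$data, file.path(outdir, "atlas.nii.gz"), geom$grid)
  write_nifti(geom$gm_parcels$data, file.path(outdir, "gm_parcels.nii.gz"),
              geom$grid)
  write_table_tsv(geom$truth, file.path(outdir, "ground_truth.tsv"))
  manifest <- load_manifest(manifest_path)
  invisible(list(manifest = manifest, geometry = geom,
                 manifest_path = manifest_path,
                 atlas_path = file.path(outdir, "atlas.nii.gz"),
                 gm_parcels_path = file.path(outdir, "gm_parcels.nii.gz")))
}

# Deterministic per-subject seed derivation; stays below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 131 * as.double(index) + 7) %%
               2147483629)
}

# Evaluate an expression under a local RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
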