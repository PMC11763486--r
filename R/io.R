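# Cohort manifest, run configuration and volume-level I/O for the pipeline.

#' Read a volume from disk
#'
#' Reads a NIfTI-1 file and returns either a `bold_run` (4-D data) or a
#' `labeled_volume` (3-D data; integer storage is preserved, so atlases and
#' masks round-trip exactly). Non-finite voxels are rejected with a message
#' naming how many there are.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param subject_id subject identifier attached to a 4-D run; defaults to
#'   the file name without extension.
#' @param tr repetition time in seconds; overrides the header value if given.
#' @return A `bold_run` (fields `data`, `grid`, `tr`, `subject_id`) or a
#'   `labeled_volume` (fields `data`, `grid`).
#' @export
read_volume <- function(path, subject_id = NULL, tr = NULL) {
  vol <- read_nifti(path)
  n_bad <- sum(!is.finite(vol$data))
  if (n_bad > 0L)
    stop("read_volume: ", n_bad, " non-finite voxel value(s) in ", path)
  if (length(dim(vol$data)) == 4L) {
    if (is.null(tr)) tr <- vol$tr
    if (is.null(subject_id))
      subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
    bold_run(vol$data, vol$grid, tr = tr, subject_id = subject_id)
  } else {
    labeled_volume(vol$data, vol$grid)
  }
}

#' One subject's 4-D BOLD run
#'
#' @param data 4-D array (x, y, z, time) of finite values.
#' @param grid a [volume_grid()].
#' @param tr repetition time in seconds (> 0).
#' @param subject_id subject identifier.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, grid, tr, subject_id = "subject") {
  stopifnot(length(dim(data)) == 4L)
  if (!identical(as.integer(dim(data)[1:3]), grid$shape))
    stop("bold_run: data does not match grid shape")
  if (dim(data)[4] < 2L) stop("bold_run: need at least 2 timepoints")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("bold_run: tr must be a positive number")
  if (anyNA(data) || any(!is.finite(data)))
    stop("bold_run: non-finite values in data")
  structure(list(data = data, grid = grid, tr = as.numeric(tr),
                 subject_id = as.character(subject_id)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run %s: %s x %d frames, TR %.3g s>\n", x$subject_id,
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4], x$tr))
}

#' A 3-D labelled or scalar volume on a grid
#'
#' @param data 3-D array; integer arrays are treated as label maps.
#' @param grid a [volume_grid()].
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(data, grid) {
  stopifnot(length(dim(data)) == 3L)
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("labeled_volume: data does not match grid shape")
  structure(list(data = data, grid = grid), class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume %s, %s>\n",
              paste(dim(x$data), collapse = "x"),
              if (is.integer(x$data)) "integer labels" else "numeric"))
}

#' Load a cohort manifest
#'
#' The manifest is a CSV with header columns `subject_id`, `bold_path`,
#' `wm_prob_path`, `gm_prob_path`, `csf_prob_path`, `group`, `tr`. Relative
#' paths are resolved against the manifest's own directory. Group labels must
#' form a two-level factor (M/F); subject ids must be unique; `tr` must be a
#' single positive value shared by the cohort.
#'
#' @param path path to the manifest CSV.
#' @param check_files if `TRUE` (default), error on unreadable referenced
#'   files.
#' @return An object of class `cohort_manifest`: a data frame of entries plus
#'   a `tr` attribute.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("load_manifest: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("load_manifest: no subjects in manifest")
  need <- c("subject_id", "bold_path", "wm_prob_path", "gm_prob_path",
            "csf_prob_path", "group", "tr")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("load_manifest: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("load_manifest: duplicate subject id(s): ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  if (any(is.na(df$group) | !nzchar(df$group)))
    stop("load_manifest: missing group label")
  groups <- unique(df$group)
  if (length(groups) > 2L)
    stop("load_manifest: group labels must form a 2-level factor, got: ",
         paste(groups, collapse = ", "))
  tr <- unique(df$tr)
  if (length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("load_manifest: tr must be a single positive value for the cohort")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  for (col in c("bold_path", "wm_prob_path", "gm_prob_path", "csf_prob_path"))
    df[[col]] <- resolve(df[[col]])
  if (check_files) {
    refs <- unlist(df[c("bold_path", "wm_prob_path", "gm_prob_path",
                        "csf_prob_path")], use.names = FALSE)
    bad <- refs[!file.exists(refs)]
    if (length(bad))
      stop("load_manifest: unreadable referenced file(s): ",
           paste(utils::head(bad, 3), collapse = ", "))
  }
  structure(df, tr = as.numeric(tr), class = c("cohort_manifest",
                                               "data.frame"))
}

#' Pipeline run configuration
#'
#' Collects the tunable parameters of the gradient pipeline. Defaults follow
#' the published analysis where a value is stated there: group-mask threshold
#' 0.95, passband 0.01-0.1 Hz, row density 0.10, diffusion anisotropy
#' alpha = 0.5, extreme-group size 30. The smoothing FWHM has no published
#' value and defaults to 0 (off).
#'
#' @param mask_threshold group-mask subject-frequency threshold in (0, 1];
#'   a voxel is kept when its frequency is `>=` the threshold.
#' @param band passband `c(low, high)` in Hz for the temporal filter.
#' @param fwhm spatial smoothing kernel FWHM in mm (0 disables smoothing).
#' @param density fraction of entries retained per connectome row.
#' @param alpha anisotropic diffusion normalization exponent in [0, 1].
#' @param n_components number of embedding components to keep.
#' @param extreme_k target size of the corpus-callosum extreme groups
#'   (clamped to half the available CC voxels at run time).
#' @param excluded_bundles character vector of bundle names dropped from the
#'   asymmetry tests.
#' @param seed integer seed controlling all pipeline randomness.
#' @param sparsify_abs rank row entries by absolute value instead of signed
#'   value when sparsifying.
#' @param fisher_z average connectomes after Fisher z-transform.
#' @param center_procrustes column-centre embeddings before Procrustes.
#' @param welch use Welch's t-test instead of the pooled-variance test.
#' @param paired use a paired t-test (not the published method).
#' @param alpha_sig significance threshold on BH-adjusted q for labelling an
#'   asymmetry direction.
#' @param smooth_before_filter run smoothing before the temporal filter.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(mask_threshold = 0.95,
                       band = c(0.01, 0.1),
                       fwhm = 0,
                       density = 0.10,
                       alpha = 0.5,
                       n_components = 3L,
                       extreme_k = 30L,
                       excluded_bundles = character(),
                       seed = 1L,
                       sparsify_abs = FALSE,
                       fisher_z = FALSE,
                       center_procrustes = FALSE,
                       welch = FALSE,
                       paired = FALSE,
                       alpha_sig = 0.05,
                       smooth_before_filter = FALSE) {
  cfg <- list(mask_threshold = mask_threshold, band = as.numeric(band),
              fwhm = fwhm, density = density, alpha = alpha,
              n_components = as.integer(n_components),
              extreme_k = as.integer(extreme_k),
              excluded_bundles = as.character(excluded_bundles),
              seed = as.integer(seed), sparsify_abs = isTRUE(sparsify_abs),
              fisher_z = isTRUE(fisher_z),
              center_procrustes = isTRUE(center_procrustes),
              welch = isTRUE(welch), paired = isTRUE(paired),
              alpha_sig = alpha_sig,
              smooth_before_filter = isTRUE(smooth_before_filter))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the numeric invariants of [run_config()]; `tr`, when supplied,
#' additionally bounds the passband by the Nyquist frequency.
#'
#' @param cfg a `run_config` or plain named list.
#' @param tr optional repetition time in seconds.
#' @return `cfg`, invisibly; errors describe the violated constraint.
#' @export
validate_config <- function(cfg, tr = NULL) {
  with(cfg, {
    if (!(mask_threshold > 0 && mask_threshold <= 1))
      stop("config: mask_threshold must be in (0, 1]")
    if (length(band) != 2L || !(band[1] >= 0 && band[1] < band[2]))
      stop("config: band must satisfy 0 <= low < high")
    if (!is.null(tr) && band[2] >= 1 / (2 * tr))
      stop("config: band high must be below the Nyquist frequency ",
           signif(1 / (2 * tr), 4), " Hz")
    if (fwhm < 0) stop("config: fwhm must be >= 0")
    if (!(density > 0 && density <= 1))
      stop("config: density must be in (0, 1]")
    if (!(alpha >= 0 && alpha <= 1)) stop("config: alpha must be in [0, 1]")
    if (n_components < 1L) stop("config: n_components must be >= 1")
    if (extreme_k < 1L) stop("config: extreme_k must be >= 1")
  })
  invisible(cfg)
}

#' Read a run configuration from a JSON file
#'
#' Field names mirror [run_config()] arguments exactly; unknown fields are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path path to a JSON file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("read_config: unknown field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

# Write a data frame as TSV (gz if the path ends in .gz).
write_table_tsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Write a numeric matrix as TSV with optional dimnames.
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m)
  if (!is.null(rownames(m))) df <- cbind(row = rownames(m), df)
  write_table_tsv(df, path)
}
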