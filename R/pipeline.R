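# End-to-end orchestration: masks -> preprocess -> connectome -> gradients ->
# asymmetry -> cc_distribution -> cc_correlation, with stage artifacts on
# disk and a machine-readable run report.

PIPELINE_STAGES <- c("masks", "preprocess", "connectome", "gradients",
                     "asymmetry", "cc_distribution", "cc_correlation")

# split paired atlas labels by hemisphere: new code = 10*code + {0 mid,1 L,2 R}
split_hemispheres <- function(atlas, label_names = NULL) {
  idx <- which(atlas$data != 0L, arr.ind = TRUE)
  hemi <- hemisphere_of(atlas$grid, idx - 1L)
  codes <- atlas$data[idx]
  side <- c(midline = 0L, L = 1L, R = 2L)[hemi]
  lab <- array(0L, dim = dim(atlas$data))
  lab[idx] <- 10L * codes + side
  base <- label_to_name(codes, label_names)
  suffix <- c(`0` = "", `1` = "_L", `2` = "_R")[as.character(side)]
  nm <- stats::setNames(paste0(base, suffix), as.character(10L * codes + side))
  nm <- nm[!duplicated(names(nm))]
  list(volume = labeled_volume(lab, atlas$grid), names = nm)
}

#' Run the full gradient pipeline on a cohort
#'
#' Executes the stages in order: per-subject tissue classification and
#' group-mask construction with atlas restriction; per-subject preprocessing
#' (CSF-mean confound regression, bandpass, optional smoothing); the WM-GM
#' Pearson connectome per subject and its group average; group-template
#' diffusion-map gradients with per-subject Procrustes alignment; the
#' per-bundle left-right asymmetry table for the AS/MS/FS cohorts; the
#' corpus-callosum gradient distributions (components 2 and 3); and the CC
#' extreme-group correlation matrices against the GM parcellation and the
#' hemisphere-split WM atlas. Every stage writes its artifacts under
#' `outdir` and the run report (`report.json`) records the configuration,
#' seed, per-stage counts and file checksums. Outputs are a pure function of
#' the inputs, configuration and seed.
#'
#' @param manifest a `cohort_manifest` from [load_manifest()].
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @param atlas_path path to the integer WM bundle atlas (NIfTI).
#' @param gm_parcels_path path to the integer GM parcellation (NIfTI).
#' @param label_names named character vector mapping atlas codes to bundle
#'   names (defaults to the synthetic atlas naming).
#' @param through_stage last stage to run (default: all).
#' @param verbose log stage progress with voxel/subject counts.
#' @return Invisibly, a list with the run `report` plus the in-memory stage
#'   results (`masks`, `template`, `aligned`, `summary`, `asymmetry`,
#'   `cc`, ...).
#' @export
run_pipeline <- function(manifest, config, outdir, atlas_path,
                         gm_parcels_path = NULL,
                         label_names = synthetic_label_names(),
                         through_stage = "cc_correlation",
                         verbose = TRUE) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  through_stage <- match.arg(through_stage, PIPELINE_STAGES)
  n_stages <- match(through_stage, PIPELINE_STAGES)
  tr <- attr(manifest, "tr")
  validate_config(config, tr = tr)   # reject a bad config before any compute
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  vlog <- function(...) if (verbose) message("wmgrad: ", ...)
  written <- character()
  put <- function(path) { written[length(written) + 1L] <<- path; path }
  stages <- list()
  res <- list(config = config)
  stage_done <- function(name, ...) {
    stages[[name]] <<- c(list(name = name, status = "complete"), list(...))
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  atlas <- read_volume(atlas_path)
  if (!inherits(atlas, "labeled_volume"))
    stop("run_pipeline: atlas must be a 3-D labelled volume")
  gm_parcels <- if (!is.null(gm_parcels_path)) read_volume(gm_parcels_path)

  ## stage 1: masks -------------------------------------------------------
  subj_masks <- NULL
  run_stage("masks", function() {
    probs <- lapply(seq_len(nrow(manifest)), function(s) {
      p <- tissue_probabilities(read_volume(manifest$wm_prob_path[s])$data,
                                read_volume(manifest$gm_prob_path[s])$data,
                                read_volume(manifest$csf_prob_path[s])$data,
                                atlas$grid)
      classify_tissues(p)
    })
    subj_masks <<- probs
    res$group_wm <<- build_group_mask(lapply(probs, `[[`, "wm"),
                                      config$mask_threshold)
    res$group_gm <<- build_group_mask(lapply(probs, `[[`, "gm"),
                                      config$mask_threshold)
    res$atlas_r <<- restrict_atlas(atlas, res$group_wm)
    if (!is.null(gm_parcels))
      res$gm_parcels_r <<- restrict_atlas(gm_parcels, res$group_gm)
    n_union <- sum(Reduce(`|`, lapply(probs, function(m) m$wm$data)))
    n_kept <- sum(res$group_wm$mask$data)
    vlog("masks: ", nrow(manifest), " subjects; WM group mask ", n_kept,
         " voxels (", n_union - n_kept, " below threshold ",
         config$mask_threshold, "); GM group mask ",
         sum(res$group_gm$mask$data), " voxels")
    write_nifti(res$group_wm$mask$data + 0L,
                put(file.path(outdir, "group_wm_mask.nii.gz")), atlas$grid)
    write_nifti(res$group_gm$mask$data + 0L,
                put(file.path(outdir, "group_gm_mask.nii.gz")), atlas$grid)
    write_nifti(res$group_wm$frequency,
                put(file.path(outdir, "group_wm_frequency.nii.gz")),
                atlas$grid)
    write_nifti(res$atlas_r$data,
                put(file.path(outdir, "atlas_restricted.nii.gz")),
                atlas$grid)
    stage_done("masks", n_subjects = nrow(manifest),
               wm_voxels = n_kept, gm_voxels = sum(res$group_gm$mask$data),
               wm_excluded = n_union - n_kept)
  })
  if (n_stages < 2L) return(.finish_report(res, stages, written, outdir,
                                           config, verbose))

  ## stage 2: preprocess --------------------------------------------------
  runs <- NULL
  run_stage("preprocess", function() {
    runs <<- lapply(seq_len(nrow(manifest)), function(s) {
      run <- read_volume(manifest$bold_path[s],
                         subject_id = manifest$subject_id[s], tr = tr)
      if (!grids_equal(run$grid, atlas$grid))
        stop("grid mismatch for subject ", manifest$subject_id[s])
      csf <- subj_masks[[s]]$csf$data
      conf <- if (any(csf)) {
        ts <- extract_timeseries(run, subj_masks[[s]]$csf)
        matrix(colMeans(ts), ncol = 1L,
               dimnames = list(NULL, "csf_mean"))
      }
      preprocess_run(run, config, confounds = conf)
    })
    vlog("preprocess: ", length(runs), " runs; band ",
         config$band[1], "-", config$band[2], " Hz, fwhm ", config$fwhm,
         " mm")
    stage_done("preprocess", n_subjects = length(runs),
               n_timepoints = dim(runs[[1]]$data)[4])
  })
  if (n_stages < 3L) return(.finish_report(res, stages, written, outdir,
                                           config, verbose))

  ## stage 3: connectome --------------------------------------------------
  fcs <- NULL
  run_stage("connectome", function() {
    wm_mask <- binary_mask(res$atlas_r$data != 0L, atlas$grid, "wm")
    gm_vol <- if (!is.null(gm_parcels)) res$gm_parcels_r$data != 0L else
      res$group_gm$mask$data
    gm_mask <- binary_mask(gm_vol, atlas$grid, "gm")
    fcs <<- lapply(runs, function(run)
      pearson_fc(extract_timeseries(run, wm_mask),
                 extract_timeseries(run, gm_mask)))
    res$fc_avg <<- average_connectomes(fcs, config$fisher_z)
    vlog("connectome: ", nrow(res$fc_avg), " WM x ", ncol(res$fc_avg),
         " GM voxels per subject")
    write_matrix_tsv(round(res$fc_avg, 10),
                     put(file.path(outdir, "group_connectome.tsv.gz")))
    write_table_tsv(as.data.frame(attr(res$fc_avg, "row_index")) |>
                      stats::setNames(c("i", "j", "k")),
                    put(file.path(outdir, "connectome_wm_voxels.tsv")))
    stage_done("connectome", wm_voxels = nrow(res$fc_avg),
               gm_voxels = ncol(res$fc_avg))
  })
  if (n_stages < 4L) return(.finish_report(res, stages, written, outdir,
                                           config, verbose))

  ## stage 4: gradients ---------------------------------------------------
  run_stage("gradients", function() {
    fit <- fit_cohort_gradients(fcs, config)
    res$template <<- fit$template
    res$aligned <<- fit$aligned
    vlog("gradients: ", ncol(fit$template$components),
         " components; variance fractions ",
         paste(sprintf("%.1f%%", 100 * fit$template$variance_fraction),
               collapse = " "))
    vi <- fit$template$voxel_index
    comp_df <- cbind(as.data.frame(vi) |> stats::setNames(c("i", "j", "k")),
                     as.data.frame(fit$template$components) |>
                       stats::setNames(paste0("g",
                                              seq_len(config$n_components))))
    write_table_tsv(comp_df, put(file.path(outdir,
                                           "template_gradients.tsv")))
    write_table_tsv(data.frame(component = seq_along(
                                 fit$template$eigenvalues),
                               eigenvalue = fit$template$eigenvalues,
                               variance_fraction =
                                 fit$template$variance_fraction),
                    put(file.path(outdir, "template_eigenvalues.tsv")))
    for (j in seq_len(config$n_components)) {
      vol <- array(0, dim = atlas$grid$shape)
      vol[vi + 1L] <- fit$template$components[, j]
      write_nifti(vol, put(file.path(outdir,
                                     sprintf("template_gradient%d.nii.gz",
                                             j))), atlas$grid)
    }
    for (s in seq_along(fit$aligned))
      write_table_tsv(as.data.frame(fit$aligned[[s]]$components) |>
                        stats::setNames(paste0("g",
                                               seq_len(config$n_components))),
                      put(file.path(outdir,
                                    sprintf("aligned_gradients_%s.tsv.gz",
                                            manifest$subject_id[s]))))
    stage_done("gradients", n_components = config$n_components,
               variance_fractions = fit$template$variance_fraction)
  })
  if (n_stages < 5L) return(.finish_report(res, stages, written, outdir,
                                           config, verbose))

  ## stage 5: asymmetry ---------------------------------------------------
  run_stage("asymmetry", function() {
    subjects <- data.frame(subject_id = manifest$subject_id,
                           group = manifest$group,
                           stringsAsFactors = FALSE)
    res$summary <<- summarize_regions(res$aligned, res$atlas_r, subjects,
                                      component = 1L,
                                      label_names = label_names,
                                      excluded_bundles =
                                        config$excluded_bundles)
    res$asymmetry <<- asymmetry_table(res$summary, config)
    n_sig <- sum(res$asymmetry$direction != "none")
    vlog("asymmetry: ", length(unique(res$asymmetry$bundle)),
         " bundles x 3 cohorts; ", n_sig, " significant direction(s)")
    write_table_tsv(res$summary, put(file.path(outdir,
                                               "region_summary.tsv")))
    write_table_tsv(res$asymmetry, put(file.path(outdir,
                                                 "asymmetry_table.tsv")))
    stage_done("asymmetry", n_bundles = length(unique(res$asymmetry$bundle)),
               n_significant = n_sig)
  })
  if (n_stages < 6L) return(.finish_report(res, stages, written, outdir,
                                           config, verbose))

  ## stage 6: cc_distribution --------------------------------------------
  run_stage("cc_distribution", function() {
    res$cc_parcel <<- cc_parcellation(res$atlas_r)
    comps <- intersect(2:3, seq_len(config$n_components))
    dists <- lapply(comps, function(cm)
      cc_distribution(res$template, res$cc_parcel, component = cm))
    names(dists) <- paste0("gradient", comps)
    res$cc_dist <<- dists
    sm <- do.call(rbind, lapply(names(dists), function(nm)
      cbind(component = nm, dists[[nm]]$summary)))
    write_table_tsv(sm, put(file.path(outdir,
                                      "cc_distribution_summary.tsv")))
    vlog("cc_distribution: ", nrow(res$cc_parcel), " CC voxels; components ",
         paste(comps, collapse = ", "))
    stage_done("cc_distribution", cc_voxels = nrow(res$cc_parcel),
               components = comps)
  })
  if (n_stages < 7L) return(.finish_report(res, stages, written, outdir,
                                           config, verbose))

  ## stage 7: cc_correlation ---------------------------------------------
  run_stage("cc_correlation", function() {
    ncc <- nrow(res$cc_parcel)
    k_eff <- min(config$extreme_k, floor(ncc / 2))
    if (k_eff < config$extreme_k)
      vlog("cc_correlation: extreme_k reduced from ", config$extreme_k,
           " to ", k_eff, " (CC has ", ncc, " voxels)")
    groups <- extreme_groups(res$template, res$cc_parcel, component = 1L,
                             k = k_eff)
    res$extreme <<- groups
    cc_bold <- group_average_bold(runs, res$cc_parcel)
    corrs <- list()
    if (!is.null(gm_parcels)) {
      gm_idx <- which(res$gm_parcels_r$data != 0L, arr.ind = TRUE) - 1L
      gm_bold <- group_average_bold(runs, gm_idx)
      gm_ts <- parcel_mean_timeseries(gm_bold, res$gm_parcels_r,
                                      parcel_names = NULL)
      rownames(gm_ts) <- sub("^region", "gm", rownames(gm_ts))
      corrs$gm <- extreme_region_correlation(groups, cc_bold, gm_ts)
    }
    hs <- split_hemispheres(res$atlas_r, label_names)
    wm_idx <- which(hs$volume$data != 0L, arr.ind = TRUE) - 1L
    wm_bold <- group_average_bold(runs, wm_idx)
    wm_ts <- parcel_mean_timeseries(wm_bold, hs$volume,
                                    parcel_names = hs$names)
    corrs$wm <- extreme_region_correlation(groups, cc_bold, wm_ts)
    res$cc_corr <<- corrs
    res$cc_compare <<- lapply(corrs, function(cr)
      compare_groups(cr$max, cr$min))
    for (nm in names(corrs)) {
      write_matrix_tsv(corrs[[nm]]$max,
                       put(file.path(outdir,
                                     sprintf("cc_corr_%s_max.tsv", nm))))
      write_matrix_tsv(corrs[[nm]]$min,
                       put(file.path(outdir,
                                     sprintf("cc_corr_%s_min.tsv", nm))))
      write_table_tsv(res$cc_compare[[nm]],
                      put(file.path(outdir,
                                    sprintf("cc_compare_%s.tsv", nm))))
    }
    memb <- array(0L, dim = atlas$grid$shape)
    memb[as.matrix(groups$min_voxels[, c("i", "j", "k")]) + 1L] <- 1L
    memb[as.matrix(groups$max_voxels[, c("i", "j", "k")]) + 1L] <- 2L
    write_nifti(memb, put(file.path(outdir, "cc_extreme_groups.nii.gz")),
                atlas$grid)
    write_table_tsv(rbind(cbind(group = "max", groups$max_voxels),
                          cbind(group = "min", groups$min_voxels)),
                    put(file.path(outdir, "cc_extreme_voxels.tsv")))
    vlog("cc_correlation: k = ", k_eff, "; ",
         paste(vapply(names(corrs), function(nm)
       paste0(nm, " ", nrow(corrs[[nm]]$max), "x", ncol(corrs[[nm]]$max)),
       ""), collapse = ", "))
    stage_done("cc_correlation", k = k_eff, cc_voxels = ncc,
               n_gm_parcels = if (!is.null(corrs$gm))
                 ncol(corrs$gm$max) else 0L,
               n_wm_parcels = ncol(corrs$wm$max))
  })
  .finish_report(res, stages, written, outdir, config, verbose)
}

.finish_report <- function(res, stages, written, outdir, config, verbose) {
  sums <- tools::md5sum(written)
  report <- list(package = "wmgrad",
                 version = as.character(utils::packageVersion("wmgrad")),
                 seed = config$seed,
                 config = unclass(config),
                 stages = unname(stages),
                 checksums = stats::setNames(unname(sums),
                                             basename(names(sums))))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (verbose) message("wmgrad: ", length(stages), " stage(s) complete; ",
                       "report written to ",
                       file.path(outdir, "report.json"))
  res$report <- report
  invisible(res)
}
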