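# Per-bundle gradient summaries and left-right asymmetry tests.

#' Summarize a gradient component per bundle and hemisphere
#'
#' Averages the chosen component over each bundle-hemisphere voxel set, per
#' subject. Hemisphere is determined from world coordinates (left = negative
#' x); voxels within one voxel of the midline are tagged `midline` (the
#' corpus callosum lands there and is excluded from L/R testing). Bundles in
#' `excluded_bundles` are omitted.
#'
#' @param aligned list of per-subject aligned `gradient_set`s sharing one
#'   voxel order.
#' @param atlas restricted `labeled_volume` of bundle labels.
#' @param subjects data frame with `subject_id` and `group`, one row per
#'   element of `aligned`, in the same order.
#' @param component which gradient component to summarize (default 1).
#' @param label_names named character vector mapping label code (name) to
#'   bundle name; unlisted codes become `region<code>`.
#' @param excluded_bundles bundle names to drop.
#' @return A `region_summary` data frame with columns `subject_id`, `group`,
#'   `bundle`, `hemisphere`, `mean_gradient`, `voxel_count`.
#' @export
summarize_regions <- function(aligned, atlas, subjects, component = 1L,
                              label_names = NULL,
                              excluded_bundles = character()) {
  stopifnot(length(aligned) == nrow(subjects))
  vi <- aligned[[1]]$voxel_index
  if (is.null(vi))
    stop("summarize_regions: gradient sets carry no voxel index")
  if (component > ncol(aligned[[1]]$components))
    stop("summarize_regions: component ", component, " not available")
  codes <- atlas$data[vi + 1L]
  if (any(codes == 0L))
    stop("summarize_regions: ", sum(codes == 0L),
         " gradient voxel(s) fall outside the atlas")
  bundle <- label_to_name(codes, label_names)
  hemi <- hemisphere_of(atlas$grid, vi)
  keep <- !(bundle %in% excluded_bundles)
  key <- interaction(bundle[keep], hemi[keep], drop = TRUE)
  rows <- lapply(seq_along(aligned), function(s) {
    v <- aligned[[s]]$components[keep, component]
    agg <- tapply(v, key, mean)
    cnt <- tapply(v, key, length)
    parts <- strsplit(names(agg), ".", fixed = TRUE)
    data.frame(subject_id = subjects$subject_id[s],
               group = subjects$group[s],
               bundle = vapply(parts, `[`, "", 1L),
               hemisphere = vapply(parts, `[`, "", 2L),
               mean_gradient = as.numeric(agg),
               voxel_count = as.integer(cnt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("region_summary", "data.frame")
  out
}

# map integer label codes to bundle names
label_to_name <- function(codes, label_names = NULL) {
  out <- paste0("region", codes)
  if (!is.null(label_names)) {
    hit <- match(as.character(codes), names(label_names))
    out[!is.na(hit)] <- label_names[hit[!is.na(hit)]]
  }
  out
}

# default name map for the synthetic atlas
synthetic_label_names <- function() {
  stats::setNames(c(paste0("bundle", 1:4), names(CC_LABELS)),
                  c(as.character(1:4), as.character(unname(CC_LABELS))))
}

# classical pooled-variance (or Welch) two-sided independent-samples t-test
pooled_t_test <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("t-test: need >= 2 observations per side")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    if (se2 == 0) {
      if (mx == my) return(list(t = 0, p = 1, df = nx + ny - 2))
      stop("t-test: zero variance with unequal means")
    }
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    t <- (mx - my) / sqrt(se2)
  } else {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    if (sp2 == 0) {
      if (mx == my) return(list(t = 0, p = 1, df = df))
      stop("t-test: zero pooled variance with unequal means")
    }
    t <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Left-right t-test for one bundle
#'
#' Two-sided independent-samples t-test comparing the per-subject left-mean
#' gradients against the per-subject right-mean gradients within a cohort
#' (`AS` = all subjects, `MS` = males, `FS` = females). Left and right means
#' of the same subjects are treated as independent samples, matching the
#' published analysis; a paired alternative is available.
#'
#' @param summary a `region_summary` from [summarize_regions()].
#' @param bundle bundle name to test.
#' @param cohort one of `"AS"`, `"MS"`, `"FS"`.
#' @param welch use Welch's unequal-variance test.
#' @param paired use a paired t-test (departure from the published method).
#' @return A list with `t`, `p`, `df`, `mean_left`, `mean_right`, `n_left`,
#'   `n_right`.
#' @export
lr_ttest <- function(summary, bundle, cohort = "AS", welch = FALSE,
                     paired = FALSE) {
  rows <- summary[summary$bundle == bundle, ]
  if (cohort == "MS") rows <- rows[rows$group == "M", ]
  if (cohort == "FS") rows <- rows[rows$group == "F", ]
  l <- rows[rows$hemisphere == "L", ]
  r <- rows[rows$hemisphere == "R", ]
  if (nrow(l) < 2L || nrow(r) < 2L)
    stop("lr_ttest: need >= 2 subjects per side for bundle ", bundle,
         " in cohort ", cohort)
  if (paired) {
    l <- l[order(l$subject_id), ]
    r <- r[order(r$subject_id), ]
    if (!identical(l$subject_id, r$subject_id))
      stop("lr_ttest: paired test needs both hemispheres for every subject")
    d <- l$mean_gradient - r$mean_gradient
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      res <- if (mean(d) == 0) list(t = 0, p = 1, df = length(d) - 1) else
        stop("lr_ttest: zero variance of paired differences, unequal means")
    } else {
      t <- mean(d) / (sd_d / sqrt(length(d)))
      res <- list(t = t, p = 2 * stats::pt(-abs(t), length(d) - 1),
                  df = length(d) - 1)
    }
  } else {
    res <- pooled_t_test(l$mean_gradient, r$mean_gradient, welch = welch)
  }
  c(res, list(mean_left = mean(l$mean_gradient),
              mean_right = mean(r$mean_gradient),
              n_left = nrow(l), n_right = nrow(r)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in input order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-bundle asymmetry table across cohorts
#'
#' Runs the left-right t-test for every tested bundle in each cohort (AS,
#' MS, FS), applies Benjamini-Hochberg correction within each cohort across
#' its bundles, and labels the asymmetry direction: `leftward` when
#' mean(L) > mean(R) with q below the significance threshold, `rightward`
#' for the reverse, `none` otherwise. Bundles without both hemispheres
#' (midline structures such as the corpus callosum) and bundles in the
#' config's exclusion list are omitted.
#'
#' @param summary a `region_summary`.
#' @param config a [run_config()] (uses `excluded_bundles`, `welch`,
#'   `paired`, `alpha_sig`).
#' @return An `asymmetry_table` data frame with columns `bundle`, `cohort`,
#'   `t`, `p`, `q`, `mean_left`, `mean_right`, `direction`.
#' @export
asymmetry_table <- function(summary, config = run_config()) {
  bundles <- sort(unique(summary$bundle))
  bundles <- setdiff(bundles, config$excluded_bundles)
  has_lr <- vapply(bundles, function(b) {
    h <- summary$hemisphere[summary$bundle == b]
    all(c("L", "R") %in% h)
  }, TRUE)
  bundles <- bundles[has_lr]
  if (length(bundles) == 0L)
    stop("asymmetry_table: no bundle has both hemispheres")
  out <- list()
  for (cohort in c("AS", "MS", "FS")) {
    res <- lapply(bundles, function(b)
      lr_ttest(summary, b, cohort, welch = config$welch,
               paired = config$paired))
    p <- vapply(res, `[[`, 0, "p")
    q <- bh_adjust(p)
    ml <- vapply(res, `[[`, 0, "mean_left")
    mr <- vapply(res, `[[`, 0, "mean_right")
    dir <- ifelse(q < config$alpha_sig,
                  ifelse(ml > mr, "leftward", "rightward"), "none")
    dir[q < config$alpha_sig & ml == mr] <- "none"
    out[[cohort]] <- data.frame(bundle = bundles, cohort = cohort,
                                t = vapply(res, `[[`, 0, "t"),
                                p = p, q = q, mean_left = ml,
                                mean_right = mr, direction = dir,
                                stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("asymmetry_table", "data.frame")
  tab
}
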