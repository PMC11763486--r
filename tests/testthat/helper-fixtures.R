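# Shared fixtures and independent oracles for the test suite.
# Everything is generated programmatically; heavier fixtures are cached in
# this environment so multiple test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small, fast world for module tests
tiny_params <- function(...) {
  defaults <- list(grid_shape = c(10L, 10L, 10L), n_per_group = 2L,
                   n_timepoints = 60L, n_networks = 6L, seed = 11L)
  do.call(synthetic_params, utils::modifyList(defaults, list(...)))
}

tiny_geometry <- function() cached("tiny_geom", make_geometry(tiny_params()))

# a simulated tiny cohort on disk (shared read-only)
tiny_cohort <- function() cached("tiny_cohort", {
  dir <- file.path(tempdir(), "wmgrad_tiny_cohort")
  simulate_cohort(tiny_params(), dir)
})

# the default-world cohort and full pipeline run at a given noise level
default_cohort_run <- function(noise_sd) {
  key <- paste0("default_run_", noise_sd)
  cached(key, {
    params <- synthetic_params(noise_sd = noise_sd)
    dir <- file.path(tempdir(), paste0("wmgrad_cohort_", noise_sd * 100))
    sim <- simulate_cohort(params, dir)
    out <- file.path(tempdir(), paste0("wmgrad_out_", noise_sd * 100))
    res <- suppressMessages(
      run_pipeline(sim$manifest, run_config(seed = 1L), out,
                   sim$atlas_path, sim$gm_parcels_path, verbose = FALSE))
    list(params = params, sim = sim, res = res, outdir = out)
  })
}

# Spearman rho between a gradient column and the planted per-subject axis
planted_axis_rho <- function(run, subject) {
  g <- run$sim$geometry
  vi <- run$res$template$voxel_index
  pos <- match(paste(vi[, 1], vi[, 2], vi[, 3]),
               paste(g$truth$i, g$truth$j, g$truth$k))
  ax <- wmgrad:::subject_axis(g, run$params,
                              run$sim$manifest$group[subject])[pos]
  stats::cor(run$res$aligned[[subject]]$components[, 1], ax,
             method = "spearman")
}

# --- independent oracles ---------------------------------------------------

# brute-force per-pair Pearson correlation
oracle_pearson <- function(a, b) {
  out <- matrix(NA_real_, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    x <- a[i, ]; y <- b[j, ]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  out
}

# direct normalized-angle formula, element by element
oracle_normalized_angle <- function(rows) {
  n <- nrow(rows)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cs <- sum(rows[i, ] * rows[j, ]) /
      (sqrt(sum(rows[i, ]^2)) * sqrt(sum(rows[j, ]^2)))
    out[i, j] <- 1 - acos(min(1, max(-1, cs))) / pi
  }
  out
}

# diffusion-map embedding via the plain (non-symmetrized) Markov operator
# and R's general eigensolver -- an independent route to the same object
oracle_diffusion_embed <- function(aff, alpha, k) {
  d <- rowSums(aff)
  w2 <- aff / outer(d^alpha, d^alpha)
  p <- w2 / rowSums(w2)
  e <- eigen(p)
  vals <- Re(e$values)
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]
  vecs <- Re(e$vectors[, ord, drop = FALSE])
  # the general solver normalizes right eigenvectors of P to unit length;
  # the multiscale convention is defined through unit-norm eigenvectors of
  # the symmetric conjugate, i.e. u_k * sqrt(d') renormalized -- map to
  # that scale, then divide by the trivial eigenvector
  d2 <- rowSums(w2)
  vhat <- vecs * sqrt(d2)
  vhat <- sweep(vhat, 2, sqrt(colSums(vhat^2)), "/")
  psi <- vhat / vhat[, 1]
  lam <- vals[-1][seq_len(k)]
  comp <- psi[, 1 + seq_len(k), drop = FALSE]
  comp <- sweep(comp, 2, lam / (1 - lam), "*")
  list(eigenvalues = lam, components = comp, lambdas_all = vals[-1])
}

# brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  qs <- vapply(seq_len(m),
               function(i) min(1, min(sp[i:m] * m / (i:m))), 0)
  q <- numeric(m)
  q[o] <- qs
  q
}

# align oracle/implementation component signs column-by-column
align_signs <- function(a, b) {
  for (j in seq_len(ncol(a)))
    if (sum(a[, j] * b[, j]) < 0) b[, j] <- -b[, j]
  b
}

# random orthogonal matrix (Haar, includes reflections)
random_orthogonal <- function(k) {
  qr.Q(qr(matrix(stats::rnorm(k * k), k)))
}

# --- replicate null-cohort machinery (type-I calibration) ------------------

# reduced null world: 10x10x10 grid, 10+10 subjects, 60 frames, no planted
# asymmetry, no ambiguous voxels
null_world <- function() cached("null_world", {
  params <- synthetic_params(grid_shape = c(10L, 10L, 10L),
                             n_per_group = 5L, n_timepoints = 60L,
                             n_networks = 6L, asym_effect = 0,
                             ambiguous_frac = 0, seed = 77L)
  geom <- make_geometry(params)
  list(params = params, geom = geom,
       wm_mask = binary_mask(geom$atlas$data != 0L, geom$grid, "wm"),
       gm_mask = binary_mask(geom$gm_parcels$data != 0L, geom$grid, "gm"),
       csf_mask = binary_mask(
         classify_tissues(tissue_probabilities(geom$tissue$wm,
                                               geom$tissue$gm,
                                               geom$tissue$csf,
                                               geom$grid))$csf$data,
         geom$grid, "csf"))
})

# one replicate cohort through the real downstream path:
# simulate -> preprocess -> connectome -> gradients -> asymmetry t-tests
null_rep_pvals <- function(rep_seed, cfg = run_config()) {
  w <- null_world()
  n <- 2L * w$params$n_per_group
  groups <- rep(c("M", "F"), each = w$params$n_per_group)
  fcs <- vector("list", n)
  for (s in seq_len(n)) {
    run <- simulate_subject(w$geom, w$params,
                            subject_seed = wmgrad:::derive_seed(rep_seed, s),
                            group = groups[s])
    csf_ts <- extract_timeseries(run, w$csf_mask)
    run <- suppressMessages(
      preprocess_run(run, cfg, confounds = matrix(colMeans(csf_ts))))
    fcs[[s]] <- pearson_fc(extract_timeseries(run, w$wm_mask),
                           extract_timeseries(run, w$gm_mask))
  }
  fit <- fit_cohort_gradients(fcs, cfg)
  subjects <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                         group = groups)
  sm <- summarize_regions(fit$aligned, w$geom$atlas, subjects,
                          component = 1L,
                          label_names = wmgrad:::synthetic_label_names())
  p <- vapply(paste0("bundle", 1:4),
              function(b) lr_ttest(sm, b, "AS")$p, 0)
  p
}
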