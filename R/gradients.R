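# The gradient machinery: row sparsification, normalized-angle affinity,
# anisotropic diffusion-map embedding, variance fractions, and group-template
# Procrustes alignment.

#' Sparsify connectome rows to a target density
#'
#' Per row, the `ceiling(density * ncol)` largest entries are retained and
#' all others set to zero. Ranking is by signed value by default (so at 10%
#' density negative correlations are effectively dropped); set `abs_rank` to
#' rank by absolute value. Ties at the cutoff are broken by lower column
#' index, which makes the retained set deterministic.
#'
#' @param fc numeric matrix (typically an `fc_matrix`).
#' @param density fraction of entries kept per row, in (0, 1].
#' @param abs_rank rank by `abs(value)` instead of signed value.
#' @return The sparsified matrix; retained entries equal the originals.
#' @export
sparsify_rows <- function(fc, density = 0.10, abs_rank = FALSE) {
  if (!(density > 0 && density <= 1))
    stop("sparsify_rows: density must be in (0, 1]")
  n <- ncol(fc)
  m <- ceiling(density * n)
  if (m >= n) return(fc)
  out <- fc
  out[] <- 0
  key <- if (abs_rank) abs(fc) else fc
  for (i in seq_len(nrow(fc))) {
    keep <- order(-key[i, ], seq_len(n))[seq_len(m)]
    out[i, keep] <- fc[i, keep]
  }
  out
}

#' Normalized-angle affinity
#'
#' For each pair of rows, the cosine similarity is mapped through
#' `s = 1 - acos(cos_sim) / pi`, giving a similarity in [0, 1]: 1 for
#' parallel rows, 0.5 for orthogonal rows, 0 for anti-parallel rows. The
#' result is symmetric with unit diagonal. All-zero rows are an error (the
#' angle is undefined).
#'
#' @param rows numeric matrix (typically sparsified connectome rows).
#' @return An `affinity_matrix` (symmetric, diagonal 1, entries in [0, 1]);
#'   the `voxel_index` row order is carried over when present.
#' @export
normalized_angle <- function(rows) {
  nrm <- sqrt(rowSums(rows^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    idx <- attr(rows, "row_index")
    where <- if (!is.null(idx))
      paste(apply(idx[bad, , drop = FALSE], 1, paste, collapse = ","),
            collapse = "; ")
    else paste(bad, collapse = ", ")
    stop("normalized_angle: all-zero row(s) at voxel(s): ", where)
  }
  u <- rows / nrm
  cs <- tcrossprod(u)
  cs <- pmin(pmax(cs, -1), 1)
  s <- 1 - acos(cs) / pi
  s <- (s + t(s)) / 2
  diag(s) <- 1
  structure(s, voxel_index = attr(rows, "row_index"),
            class = c("affinity_matrix", "matrix", "array"))
}

check_affinity <- function(aff, tol = 1e-10) {
  if (nrow(aff) != ncol(aff)) stop("affinity must be square")
  if (max(abs(aff - t(aff))) > tol)
    stop("affinity not symmetric within ", tol)
  if (any(aff < -tol | aff > 1 + tol))
    stop("affinity entries outside [0, 1]")
  invisible(TRUE)
}

#' A set of embedding gradients
#'
#' Container for the output of [diffusion_embed()]: per-voxel component
#' scores, the corresponding eigenvalues, variance fractions over the
#' retained non-trivial spectrum, and the row (voxel) order.
#'
#' @param components n x k numeric matrix of gradient scores.
#' @param eigenvalues k eigenvalues, sorted non-increasing.
#' @param lambdas_all all retained non-trivial eigenvalues (variance
#'   denominator).
#' @param voxel_index optional n x 3 matrix of 0-based voxel indices.
#' @param aligned has the set been Procrustes-aligned to a template?
#' @return An object of class `gradient_set`.
#' @export
gradient_set <- function(components, eigenvalues, lambdas_all = eigenvalues,
                         voxel_index = NULL, aligned = FALSE) {
  components <- as.matrix(components)
  k <- ncol(components)
  stopifnot(length(eigenvalues) == k)
  if (k > 1L && any(diff(eigenvalues) > 1e-12))
    stop("gradient_set: eigenvalues must be sorted non-increasing")
  structure(list(components = components,
                 eigenvalues = as.numeric(eigenvalues),
                 variance_fraction = variance_fractions(eigenvalues,
                                                        lambdas_all),
                 lambdas_all = as.numeric(lambdas_all),
                 voxel_index = voxel_index,
                 aligned = isTRUE(aligned)),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set %d voxels x %d components%s; var: %s>\n",
              nrow(x$components), ncol(x$components),
              if (x$aligned) ", aligned" else "",
              paste(sprintf("%.1f%%", 100 * x$variance_fraction),
                    collapse = " ")))
}

#' Variance fraction of each gradient
#'
#' Defined as `lambda_k / sum(lambda_j)` over all retained non-trivial
#' eigenvalues that are positive. This is the quantity quoted as "percent
#' variance" per gradient; note the denominator depends on how many
#' eigenvalues were retained.
#'
#' @param eigenvalues eigenvalues of the reported components.
#' @param all_eigenvalues the full retained non-trivial spectrum.
#' @return Numeric vector of fractions (non-negative, sum <= 1).
#' @export
variance_fractions <- function(eigenvalues, all_eigenvalues = eigenvalues) {
  pos <- all_eigenvalues[all_eigenvalues > 0]
  if (length(pos) == 0L)
    stop("variance_fractions: all eigenvalues <= 0")
  pmax(eigenvalues, 0) / sum(pos)
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Forms the anisotropic operator `W' = D^-alpha W D^-alpha` (D = diagonal
#' row sums of W), row-normalizes it to a Markov matrix `P`, and returns the
#' leading non-trivial right eigenvectors of `P`. The eigendecomposition is
#' performed on the symmetric conjugate `D'^(1/2) P D'^(-1/2)`, which
#' guarantees a real spectrum, and mapped back. Components follow the
#' diffusion-time-zero multiscale convention: eigenvector `psi_k` (scaled so
#' the trivial eigenvector is the constant 1) times `lambda_k / (1 -
#' lambda_k)`; `raw = TRUE` returns unscaled eigenvectors. With alpha = 0.5
#' the operator approximates the Laplace-Beltrami geometry of the data
#' irrespective of sampling density, preserving global relationships.
#'
#' Each component's sign is fixed so its largest-magnitude loading is
#' positive (`fix_sign`), making runs comparable; eigenvector sign is
#' otherwise arbitrary.
#'
#' @param aff symmetric non-negative affinity matrix.
#' @param alpha anisotropic normalization exponent in [0, 1].
#' @param k number of non-trivial components to return (`k < n`).
#' @param raw return unscaled eigenvectors.
#' @param fix_sign apply the deterministic sign convention.
#' @return A [gradient_set()].
#' @export
diffusion_embed <- function(aff, alpha = 0.5, k = 3L, raw = FALSE,
                            fix_sign = TRUE) {
  aff <- unclass(aff)
  n <- nrow(aff)
  if (k >= n) stop("diffusion_embed: k must be < n")
  if (!(alpha >= 0 && alpha <= 1))
    stop("diffusion_embed: alpha must be in [0, 1]")
  if (max(abs(aff - t(aff))) > 1e-10)
    stop("diffusion_embed: affinity not symmetric")
  aff <- (aff + t(aff)) / 2
  d <- rowSums(aff)
  if (any(d <= 0)) stop("diffusion_embed: zero-degree row(s)")
  da <- d^(-alpha)
  w2 <- aff * outer(da, da)
  d2 <- rowSums(w2)
  s <- w2 * outer(1 / sqrt(d2), 1 / sqrt(d2))
  es <- eigen(s, symmetric = TRUE)
  vals <- es$values
  if (sum(vals > 1 - 1e-8) > 1L)
    stop("diffusion_embed: similarity graph is disconnected ",
         "(multiple eigenvalues at 1)")
  # right eigenvectors of P, scaled so the trivial one is the constant 1
  psi <- es$vectors / sqrt(d2)
  psi <- psi / psi[, 1]
  lam_all <- vals[-1]
  keep <- lam_all[seq_len(k)]
  comp <- psi[, 1 + seq_len(k), drop = FALSE]
  if (!raw) {
    scale <- keep / (1 - keep)
    comp <- sweep(comp, 2, scale, "*")
  }
  if (fix_sign) {
    for (j in seq_len(k)) {
      v <- comp[, j]
      if (v[which.max(abs(v))] < 0) comp[, j] <- -v
    }
  }
  gradient_set(comp, keep, lambdas_all = lam_all,
               voxel_index = attr(aff, "voxel_index"))
}

#' Procrustes alignment of a subject to a template
#'
#' Finds the orthogonal matrix R (rotations and reflections) minimizing
#' `||subject R - template||_F` and applies it. There is no scaling and,
#' unless `center` is set, no translation, so the alignment is an isometry of
#' the subject's embedding: pairwise row distances are preserved exactly. A
#' rank-deficient cross-covariance is flagged with a warning (the
#' reflection-inclusive SVD solution is still returned).
#'
#' @param subject,template `gradient_set` objects with equal dimensions.
#' @param center column-centre both embeddings first.
#' @return The aligned `gradient_set` (`aligned = TRUE`), carrying the
#'   rotation as attribute `rotation`.
#' @export
procrustes_align <- function(subject, template, center = FALSE) {
  x <- subject$components
  y <- template$components
  if (!all(dim(x) == dim(y)))
    stop("procrustes_align: dimension mismatch (",
         paste(dim(x), collapse = "x"), " vs ",
         paste(dim(y), collapse = "x"), ")")
  if (center) {
    x <- sweep(x, 2, colMeans(x))
    y <- sweep(y, 2, colMeans(y))
  }
  m <- crossprod(x, y)
  sv <- svd(m)
  if (min(sv$d) < max(sv$d) * 1e-12)
    warning("procrustes_align: rank-deficient cross-covariance; ",
            "solution not unique")
  r <- sv$u %*% t(sv$v)
  out <- gradient_set(subject$components %*% r, subject$eigenvalues,
                      lambdas_all = subject$lambdas_all,
                      voxel_index = subject$voxel_index, aligned = TRUE)
  attr(out, "rotation") <- r
  out
}

#' Group-template gradients with per-subject alignment
#'
#' Implements the two-step group scheme: (1) embed the subject-averaged
#' connectome to obtain the group template, then (2) embed each subject's own
#' connectome identically and Procrustes-align it to the template.
#'
#' @param fcs list of per-subject `fc_matrix` objects on consistent voxel
#'   indices.
#' @param config a [run_config()] (uses `density`, `alpha`, `n_components`,
#'   `sparsify_abs`, `fisher_z`, `center_procrustes`).
#' @return A list with `template` (a `gradient_set`) and `aligned` (list of
#'   per-subject aligned `gradient_set`s).
#' @export
fit_cohort_gradients <- function(fcs, config = run_config()) {
  embed_one <- function(fc) {
    diffusion_embed(normalized_angle(sparsify_rows(fc, config$density,
                                                   config$sparsify_abs)),
                    alpha = config$alpha, k = config$n_components)
  }
  template <- embed_one(average_connectomes(fcs, config$fisher_z))
  aligned <- lapply(fcs, function(fc)
    procrustes_align(embed_one(fc), template,
                     center = config$center_procrustes))
  list(template = template, aligned = aligned)
}
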