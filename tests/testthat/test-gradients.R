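# Sparsification, normalized-angle kernel, diffusion embedding, variance
# fractions and Procrustes alignment.

test_that("sparsify_rows keeps the top entries per row, deterministically", {
  row10 <- matrix(c(3, 9, 1, 4, 8, 2, 7, 5, 6, 0), 1)
  s <- sparsify_rows(row10, 0.1)
  expect_equal(sum(s != 0), 1L)
  expect_equal(s[1, 2], 9)

  m <- matrix(rnorm(30 * 200), 30)
  expect_identical(sparsify_rows(m, 1), m)

  s2 <- sparsify_rows(m, 0.1)
  for (i in 1:30) {
    kept <- which(s2[i, ] != 0)
    expect_equal(length(kept), 20L)
    # full-sort oracle: the kept set is the 20 largest values
    expect_setequal(kept, order(m[i, ], decreasing = TRUE)[1:20])
    expect_equal(s2[i, kept], m[i, kept])
  }

  # ties at the cutoff: lower column index wins
  tied <- matrix(c(1, 5, 5, 5, 0, 0, 0, 0, 0, 0), 1)
  st <- sparsify_rows(tied, 0.2)
  expect_equal(which(st[1, ] != 0), c(2L, 3L))

  # absolute-value ranking flag
  sm <- matrix(c(-9, 1, 2, 3, 4, 5, 6, 7, 8, 0), 1)
  expect_equal(which(sparsify_rows(sm, 0.1, abs_rank = TRUE)[1, ] != 0), 1L)
  expect_equal(which(sparsify_rows(sm, 0.1)[1, ] != 0), 9L)

  expect_error(sparsify_rows(m, 0), "density")
})

test_that("normalized_angle: parallel 1, orthogonal 0.5, antiparallel 0", {
  rows <- rbind(c(1, 0, 0, 2), 3 * c(1, 0, 0, 2), c(0, 1, -2, 0),
                -c(1, 0, 0, 2))
  s <- normalized_angle(rows)
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], 0.5)
  expect_equal(s[1, 4], 0)
  expect_equal(diag(s), rep(1, 4))
  expect_error(normalized_angle(rbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("two-block affinity: gradient 1 is the block indicator", {
  blocks <- matrix(0.5, 8, 8)
  blocks[1:4, 1:4] <- 1
  blocks[5:8, 5:8] <- 1
  emb <- diffusion_embed(blocks, alpha = 0.5, k = 2)
  g1 <- emb$components[, 1]
  expect_lt(diff(range(g1[1:4])), 1e-10)
  expect_lt(diff(range(g1[5:8])), 1e-10)
  expect_lt(g1[1] * g1[5], 0)
  # oracle agreement on the same 8x8 operator
  orc <- oracle_diffusion_embed(blocks, 0.5, 2)
  expect_equal(emb$eigenvalues, orc$eigenvalues, tolerance = 1e-10)
  expect_equal(align_signs(emb$components, orc$components),
               emb$components, tolerance = 1e-8)
})

test_that("alpha = 0 equals the plain Markov operator embedding", {
  set.seed(5)
  r <- matrix(runif(100), 10)
  aff <- (r + t(r)) / 2; diag(aff) <- 1
  emb <- diffusion_embed(aff, alpha = 0, k = 3)
  orc <- oracle_diffusion_embed(aff, 0, 3)   # D^0 = identity inside
  expect_equal(emb$eigenvalues, orc$eigenvalues, tolerance = 1e-10)
  expect_equal(align_signs(emb$components, orc$components),
               emb$components, tolerance = 1e-8)
})

test_that("embedding is invariant to affinity scale and rejects bad input", {
  set.seed(6)
  r <- matrix(runif(144), 12)
  aff <- (r + t(r)) / 2; diag(aff) <- 1
  e1 <- diffusion_embed(aff, 0.5, 3)
  e2 <- diffusion_embed(0.37 * aff, 0.5, 3)
  expect_equal(e1$eigenvalues, e2$eigenvalues, tolerance = 1e-10)
  expect_equal(e1$components, e2$components, tolerance = 1e-8)

  expect_error(diffusion_embed(matrix(runif(9), 3), 0.5, 1),
               "not symmetric")
  disc <- diag(4) * 0 + diag(4)
  disc[1:2, 1:2] <- 1; disc[3:4, 3:4] <- 1   # two components
  expect_error(diffusion_embed(disc, 0.5, 1), "disconnected")
  expect_error(diffusion_embed(aff, 0.5, 12), "k must be")
})

test_that("variance fractions are the eigenvalue ratios", {
  expect_equal(variance_fractions(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(variance_fractions(5), 1)
  set.seed(8)
  lam <- sort(runif(10), decreasing = TRUE)
  expect_equal(variance_fractions(lam[1:3], lam), lam[1:3] / sum(lam),
               tolerance = 1e-15)
  expect_error(variance_fractions(c(-1, -2)), "eigenvalues")
})

test_that("Procrustes: identity, rotation recovery, reflections, isometry", {
  set.seed(9)
  comp <- matrix(rnorm(60 * 3), 60)
  template <- gradient_set(comp, c(0.3, 0.2, 0.1))

  same <- procrustes_align(template, template)
  expect_equal(same$components, comp, tolerance = 1e-10)
  expect_equal(attr(same, "rotation"), diag(3), tolerance = 1e-10)

  q <- random_orthogonal(3)
  rot <- gradient_set(comp %*% q, c(0.3, 0.2, 0.1))
  back <- procrustes_align(rot, template)
  expect_equal(back$components, comp, tolerance = 1e-10)

  flip <- gradient_set(comp %*% diag(c(-1, 1, -1)), c(0.3, 0.2, 0.1))
  expect_equal(procrustes_align(flip, template)$components, comp,
               tolerance = 1e-10)

  # alignment preserves pairwise row distances (isometry)
  noisy <- gradient_set(comp %*% q + 0.05 * matrix(rnorm(180), 60),
                        c(0.3, 0.2, 0.1))
  al <- procrustes_align(noisy, template)
  d0 <- dist(noisy$components)
  expect_equal(as.numeric(dist(al$components)), as.numeric(d0),
               tolerance = 1e-10)
  # and never increases the Frobenius distance to the template
  expect_lte(norm(al$components - comp, "F"),
             norm(noisy$components - comp, "F") + 1e-12)

  expect_error(procrustes_align(gradient_set(comp[, 1:2], c(0.3, 0.2)),
                                template), "dimension mismatch")
})

test_that("cohort fitting: degenerate cohort and permutation invariance", {
  set.seed(10)
  mk <- function(m) structure(m, row_index = NULL, col_index = NULL,
                              class = c("fc_matrix", "matrix", "array"))
  base <- matrix(runif(40 * 60, -0.2, 0.9), 40)
  cfg <- run_config(n_components = 2L)

  fit_same <- fit_cohort_gradients(list(mk(base), mk(base), mk(base)), cfg)
  for (a in fit_same$aligned) {
    expect_true(a$aligned)
    expect_equal(a$components, fit_same$template$components,
                 tolerance = 1e-8)
  }

  fcs <- lapply(1:4, function(i)
    mk(base + matrix(runif(40 * 60, -0.05, 0.05), 40)))
  f1 <- fit_cohort_gradients(fcs, cfg)
  f2 <- fit_cohort_gradients(rev(fcs), cfg)
  expect_equal(f1$template$components, f2$template$components,
               tolerance = 1e-10)
})
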