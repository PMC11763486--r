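# Tissue classification, group masks, atlas restriction and signal cleaning.

test_that("classify_tissues assigns argmax with WM > GM > CSF tie priority", {
  grid <- volume_grid(c(2L, 2L, 1L))
  wm <- array(c(0.7, 0.4, 0.1, 1 / 3), dim = c(2, 2, 1))
  gm <- array(c(0.2, 0.4, 0.7, 1 / 3), dim = c(2, 2, 1))
  csf <- array(c(0.1, 0.2, 0.2, 1 / 3), dim = c(2, 2, 1))
  masks <- classify_tissues(tissue_probabilities(wm, gm, csf, grid))
  expect_true(masks$wm$data[1, 1, 1])     # plain argmax
  expect_true(masks$wm$data[2, 1, 1])     # WM/GM tie -> WM
  expect_true(masks$gm$data[1, 2, 1])
  expect_true(masks$wm$data[2, 2, 1])     # three-way tie -> WM
  # partition: union covers, intersections empty
  tot <- masks$wm$data + masks$gm$data + masks$csf$data
  expect_true(all(tot == 1L))
})

test_that("group mask thresholding uses >= and is monotone in threshold", {
  grid <- volume_grid(c(3L, 1L, 1L))
  # voxel frequencies 0.94, 0.95, 1.0 over 100 subjects
  masks <- lapply(1:100, function(s)
    binary_mask(array(c(s <= 94, s <= 95, TRUE), dim = c(3, 1, 1)),
                grid, "wm"))
  gm <- build_group_mask(masks, 0.95)
  expect_equal(gm$frequency[, 1, 1], c(0.94, 0.95, 1.0))
  expect_equal(gm$mask$data[, 1, 1], c(FALSE, TRUE, TRUE))

  # monotone: raising the threshold never adds voxels
  kept <- sapply(c(0.5, 0.8, 0.94, 0.95, 0.99, 1),
                 function(th) sum(build_group_mask(masks, th)$mask$data))
  expect_true(all(diff(kept) <= 0))

  expect_error(build_group_mask(list(masks[[1]],
                                     binary_mask(array(TRUE, c(2, 1, 1)),
                                                 volume_grid(c(2L, 1L, 1L)),
                                                 "wm")), 0.5),
               "grid mismatch")
})

test_that("restrict_atlas zeroes outside the mask and names lost labels", {
  geom <- tiny_geometry()
  all_true <- binary_mask(array(TRUE, dim = geom$grid$shape), geom$grid,
                          "wm")
  r <- restrict_atlas(geom$atlas, all_true)
  expect_identical(r$data, geom$atlas$data)

  # drop one bundle entirely -> error naming its label
  lab1 <- geom$atlas$data == 1L
  partial <- binary_mask(array(TRUE, dim = geom$grid$shape) & !lab1,
                         geom$grid, "wm")
  expect_error(restrict_atlas(geom$atlas, partial), "1")

  # surviving counts match brute-force recount under a random mask
  set.seed(42)
  keepv <- array(runif(prod(geom$grid$shape)) < 0.9,
                 dim = geom$grid$shape)
  keepv[geom$atlas$data == 2L][1] <- TRUE  # keep every label alive
  for (code in sort(unique(geom$atlas$data[geom$atlas$data != 0])))
    keepv[which(geom$atlas$data == code)[1]] <- TRUE
  rm2 <- restrict_atlas(geom$atlas, binary_mask(keepv, geom$grid, "wm"))
  counts <- attr(rm2, "counts")
  for (code in names(counts))
    expect_equal(counts[[code]],
                 sum(geom$atlas$data == as.integer(code) & keepv))
})

test_that("confound regression matches a normal-equations oracle", {
  grid <- volume_grid(c(2L, 2L, 2L))
  set.seed(7)
  tt <- 40L
  arr <- array(rnorm(8 * tt), dim = c(2, 2, 2, tt))
  run <- bold_run(arr, grid, tr = 1)
  conf <- cbind(sin(1:tt / 3), rnorm(tt))

  out <- regress_confounds(run, conf)
  x <- cbind(1, conf)
  in_mat <- matrix(arr, 8, tt)
  out_mat <- matrix(out$data, 8, tt)
  for (v in 1:4) {
    y <- in_mat[v, ]
    beta <- solve(t(x) %*% x, t(x) %*% y)   # independent OLS solve
    expect_equal(out_mat[v, ], as.numeric(y - x %*% beta),
                 tolerance = 1e-10)
  }
  # residuals orthogonal to every confound column
  res_mat <- matrix(out$data, 8, tt)
  orth <- abs(res_mat %*% conf) / (sqrt(rowSums(res_mat^2)) %o%
                                     sqrt(colSums(conf^2)))
  expect_lt(max(orth), 1e-8)

  # a series equal to a confound regresses to zero
  arr2 <- arr
  arr2[1, 1, 1, ] <- 3 * conf[, 1] + 2
  out2 <- regress_confounds(bold_run(arr2, grid, tr = 1), conf)
  expect_lt(max(abs(out2$data[1, 1, 1, ])), 1e-10)

  # no confounds: demeaning only
  out3 <- regress_confounds(run, NULL)
  expect_equal(out3$data[2, 1, 1, ], arr[2, 1, 1, ] - mean(arr[2, 1, 1, ]),
               tolerance = 1e-12)

  expect_error(regress_confounds(run, cbind(conf[, 1], conf[, 1])),
               "rank-deficient")
  expect_error(regress_confounds(run, conf[1:10, ]), "rows")
})

test_that("bandpass keeps in-band sinusoids, kills DC and out-of-band", {
  grid <- volume_grid(c(1L, 1L, 1L))
  tt <- 200L; tr <- 0.72
  tim <- (0:(tt - 1)) * tr
  mk <- function(y) bold_run(array(y, dim = c(1, 1, 1, tt)), grid, tr = tr)
  amp <- function(run) sd(run$data[1, 1, 1, ])

  inband <- sin(2 * pi * 0.05 * tim)
  out <- bandpass_filter(mk(inband), 0.01, 0.1)
  expect_gte(amp(out) / sd(inband), 0.9)
  # zero phase: filtered series stays aligned with the input
  expect_gt(cor(out$data[1, 1, 1, ], inband), 0.99)

  fast <- sin(2 * pi * 0.4 * tim)
  expect_lte(amp(bandpass_filter(mk(fast), 0.01, 0.1)) / sd(fast), 0.1)

  const <- rep(5, tt)
  expect_lt(max(abs(bandpass_filter(mk(const), 0.01, 0.1)$data)), 1e-10)

  expect_error(bandpass_filter(mk(inband), 0.01, 0.8), "Nyquist|invalid")
})

test_that("spatial smoothing: identity, uniform preservation, kernel", {
  grid <- volume_grid(c(7L, 7L, 7L))
  arr <- array(rnorm(7^3 * 2), dim = c(7, 7, 7, 2))
  run <- bold_run(arr, grid, tr = 1)
  expect_identical(spatial_smooth(run, 0)$data, arr)

  unif <- bold_run(array(2.5, dim = c(7, 7, 7, 2)), grid, tr = 1)
  sm <- spatial_smooth(unif, 4)
  expect_lt(max(abs(sm$data - 2.5)), 1e-10)   # everywhere, incl. boundary

  # impulse response matches the separable Gaussian kernel weights
  imp <- array(0, dim = c(7, 7, 7, 2))
  imp[4, 4, 4, 1] <- 1
  fwhm <- 3
  smi <- spatial_smooth(bold_run(imp, grid, tr = 1), fwhm)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / 2   # voxel units (2 mm voxels)
  r <- ceiling(3 * sigma)
  g <- exp(-(-r:r)^2 / (2 * sigma^2)); g <- g / sum(g)
  expect_equal(smi$data[4, 4, 4, 1], g[r + 1]^3, tolerance = 1e-10)
  expect_equal(smi$data[4 + 1, 4, 4, 1], g[r + 2] * g[r + 1]^2,
               tolerance = 1e-10)
  expect_equal(smi$data[4 + 1, 4 - 1, 4, 1], g[r + 2]^2 * g[r + 1],
               tolerance = 1e-10)
})

test_that("classify_tissues recovers the generator partition exactly", {
  geom <- make_geometry(tiny_params(ambiguous_frac = 0))
  masks <- classify_tissues(tissue_probabilities(geom$tissue$wm,
                                                 geom$tissue$gm,
                                                 geom$tissue$csf,
                                                 geom$grid))
  wm_expected <- geom$tissue$wm > 0.5
  expect_identical(masks$wm$data, wm_expected)
})
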