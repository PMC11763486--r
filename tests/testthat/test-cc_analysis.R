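# Corpus-callosum distributions, extreme groups and parcel correlations.

test_that("cc_distribution partitions the CC and summarizes per sublabel", {
  run <- default_cohort_run(0.5)
  res <- run$res
  parcel <- cc_parcellation(res$atlas_r)
  expect_setequal(unique(parcel$sublabel), c("genu", "body", "splenium"))

  d <- cc_distribution(res$template, parcel, component = 2L)
  expect_equal(sum(vapply(d$values, length, 0L)), nrow(parcel))
  expect_equal(sum(d$summary$n), nrow(parcel))
  expect_equal(colSums(d$histogram),
               setNames(vapply(d$values, length, 0L), colnames(d$histogram)))

  # constant gradient: all sublabel collections concentrate at one value
  tpl <- res$template
  tpl$components[, 2] <- 1.25
  dc <- cc_distribution(tpl, parcel, component = 2L)
  expect_true(all(vapply(dc$values, function(v) all(v == 1.25), TRUE)))

  # planted sublabel index is perfectly separated
  code <- match(parcel$sublabel, c("genu", "body", "splenium"))
  tpl2 <- res$template
  pos <- wmgrad:::.match_cc_rows(tpl2, parcel)
  tpl2$components[pos, 2] <- code
  d2 <- cc_distribution(tpl2, parcel, component = 2L)
  expect_true(all(d2$values$genu == 1))
  expect_true(all(d2$values$body == 2))
  expect_true(all(d2$values$splenium == 3))

  expect_error(cc_distribution(res$template, parcel, component = 9L),
               "component")
})

test_that("extreme_groups are order statistics with deterministic ties", {
  run <- default_cohort_run(0.5)
  res <- run$res
  parcel <- cc_parcellation(res$atlas_r)
  n <- nrow(parcel)

  # plant the values 1..n in canonical order
  tpl <- res$template
  pos <- wmgrad:::.match_cc_rows(tpl, parcel)
  tpl$components[pos, 1] <- seq_len(n)
  eg <- extreme_groups(tpl, parcel, component = 1L, k = 30L)
  expect_setequal(eg$max_voxels$value, (n - 29):n)
  expect_setequal(eg$min_voxels$value, 1:30)
  expect_gte(min(eg$max_voxels$value), max(eg$min_voxels$value))

  # boundary: k = n/2 partitions the CC
  eg2 <- extreme_groups(tpl, parcel, component = 1L, k = n %/% 2)
  expect_equal(nrow(eg2$max_voxels) + nrow(eg2$min_voxels),
               2 * (n %/% 2))
  expect_equal(length(intersect(eg2$max_voxels$row, eg2$min_voxels$row)), 0L)
  expect_error(extreme_groups(tpl, parcel, component = 1L, k = n),
               "exceeds")

  # random values match a full-sort oracle; negation swaps the groups
  set.seed(13)
  tpl$components[pos, 1] <- rnorm(n)
  v <- tpl$components[pos, 1]
  eg3 <- extreme_groups(tpl, parcel, component = 1L, k = 10L)
  expect_setequal(eg3$max_voxels$value, sort(v, decreasing = TRUE)[1:10])
  expect_setequal(eg3$min_voxels$value, sort(v)[1:10])
  tpl_neg <- tpl
  tpl_neg$components[, 1] <- -tpl$components[, 1]
  eg4 <- extreme_groups(tpl_neg, parcel, component = 1L, k = 10L)
  expect_equal(eg4$max_voxels[, c("i", "j", "k")],
               eg3$min_voxels[, c("i", "j", "k")])
  expect_equal(eg4$min_voxels[, c("i", "j", "k")],
               eg3$max_voxels[, c("i", "j", "k")])
})

test_that("group_average_bold averages voxelwise with strict checks", {
  grid <- volume_grid(c(2L, 2L, 1L))
  mk <- function(x) bold_run(array(x, dim = c(2, 2, 1, 4)), grid, tr = 1)
  set.seed(14)
  x <- array(rnorm(16), dim = c(2, 2, 1, 4))
  vox <- rbind(c(0, 0, 0), c(1, 1, 0))

  one <- group_average_bold(list(mk(x)), vox)
  expect_equal(one[1, ], x[1, 1, 1, ])
  expect_equal(one[2, ], x[2, 2, 1, ])

  zero <- group_average_bold(list(mk(x), mk(-x)), vox)
  expect_equal(max(abs(zero)), 0)

  y <- array(rnorm(16), dim = c(2, 2, 1, 4))
  z <- array(rnorm(16), dim = c(2, 2, 1, 4))
  avg <- group_average_bold(list(mk(x), mk(y), mk(z)), vox)
  expect_equal(avg[1, ], (x[1, 1, 1, ] + y[1, 1, 1, ] + z[1, 1, 1, ]) / 3,
               tolerance = 1e-15)

  short <- bold_run(array(rnorm(8), dim = c(2, 2, 1, 2)), grid, tr = 1)
  expect_error(group_average_bold(list(mk(x), short), vox), "unequal")
  expect_error(group_average_bold(list(mk(x)), rbind(c(5, 0, 0))),
               "outside")
})

test_that("parcel_mean_timeseries is a group-by mean over parcels", {
  grid <- volume_grid(c(3L, 1L, 1L))
  lab <- labeled_volume(array(c(1L, 1L, 2L), dim = c(3, 1, 1)), grid)
  bold <- matrix(rnorm(12), 3)
  attr(bold, "voxel_index") <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  ts <- parcel_mean_timeseries(bold, lab)
  expect_equal(ts[1, ], colMeans(bold[1:2, ]))
  expect_equal(ts[2, ], bold[3, ])   # singleton parcel = its own series

  # idempotent mean for identical-signal voxels
  bold2 <- bold; bold2[2, ] <- bold2[1, ]
  attr(bold2, "voxel_index") <- attr(bold, "voxel_index")
  expect_equal(parcel_mean_timeseries(bold2, lab)[1, ], bold2[1, ])

  # empty parcel is an error naming it
  bold3 <- bold[3, , drop = FALSE]
  attr(bold3, "voxel_index") <- rbind(c(2, 0, 0))
  expect_error(parcel_mean_timeseries(bold3, lab), "region1")
})

test_that("extreme_region_correlation shapes, bounds and self-correlation", {
  run <- default_cohort_run(0.5)
  res <- run$res
  expect_equal(dim(res$cc_corr$gm$max), c(30L, 8L))
  expect_equal(dim(res$cc_corr$gm$min), c(30L, 8L))
  expect_equal(dim(res$cc_corr$wm$max), c(30L, 11L))
  for (m in c(res$cc_corr$gm, res$cc_corr$wm))
    expect_true(all(m >= -1 & m <= 1))

  # a parcel series equal to a voxel series correlates at exactly 1
  groups <- res$extreme
  parcel <- res$cc_parcel
  cc_bold <- group_average_bold(
    lapply(seq_len(nrow(run$sim$manifest)), function(s)
      read_volume(run$sim$manifest$bold_path[s], tr = 0.72)), parcel)
  fake <- cc_bold[match(groups$max_voxels$row,
                        wmgrad:::.match_cc_rows(res$template, parcel))[1:2], ,
                  drop = FALSE]
  rownames(fake) <- c("pA", "pB")
  rc <- extreme_region_correlation(groups, cc_bold, fake)
  expect_equal(unname(rc$max[1, "pA"]), 1)
  expect_equal(unname(rc$max[2, "pB"]), 1)
})

test_that("compare_groups differences and exception flags", {
  set.seed(15)
  a <- matrix(runif(50, 0, 0.8), 10); colnames(a) <- paste0("p", 1:5)
  expect_true(all(compare_groups(a, a)$difference == 0))
  expect_false(any(compare_groups(a, a)$min_gt_max))

  b <- a * 0.5
  b[, 3] <- a[, 3] + 0.1               # plant one exception parcel
  cg <- compare_groups(a, b)
  expect_equal(cg$parcel[cg$min_gt_max], "p3")
  expect_equal(cg$difference, colMeans(a) - colMeans(b), ignore_attr = TRUE)

  colnames(b) <- paste0("q", 1:5)
  expect_error(compare_groups(a, b), "parcel sets")
})
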