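# Region summaries, left-right t-tests, BH correction, asymmetry table.

# build a region_summary directly (summary-level world)
mk_summary <- function(n_per_side, bundles, means_l, means_r, sd = 1,
                       groups = NULL) {
  rows <- list()
  if (is.null(groups)) groups <- rep(c("M", "F"), length.out = n_per_side)
  for (b in seq_along(bundles)) for (s in seq_len(n_per_side)) {
    sid <- sprintf("s%02d", s)
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = sid, group = groups[s], bundle = bundles[b],
      hemisphere = c("L", "R"),
      mean_gradient = c(rnorm(1, means_l[b], sd), rnorm(1, means_r[b], sd)),
      voxel_count = 10L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("region_summary", "data.frame")
  out
}

test_that("summarize_regions means match a brute-force group-by", {
  run <- default_cohort_run(0.5)
  res <- run$res
  subjects <- data.frame(subject_id = run$sim$manifest$subject_id,
                         group = run$sim$manifest$group)
  sm <- summarize_regions(res$aligned, res$atlas_r, subjects, component = 1L,
                          label_names = wmgrad:::synthetic_label_names())
  vi <- res$template$voxel_index
  codes <- res$atlas_r$data[vi + 1L]
  hemi <- hemisphere_of(res$atlas_r$grid, vi)
  names_map <- wmgrad:::synthetic_label_names()
  for (s in c(1L, 4L)) {
    v <- res$aligned[[s]]$components[, 1]
    for (b in c("bundle2", "cc_genu")) {
      for (h in unique(hemi[names_map[as.character(codes)] == b])) {
        sel <- names_map[as.character(codes)] == b & hemi == h
        row <- sm[sm$subject_id == subjects$subject_id[s] &
                    sm$bundle == b & sm$hemisphere == h, ]
        expect_equal(row$mean_gradient, mean(v[sel]), tolerance = 1e-12)
        expect_equal(row$voxel_count, sum(sel))
      }
    }
  }
  # constant gradient -> every mean equals the constant
  const <- res$aligned
  for (i in seq_along(const))
    const[[i]]$components[, 1] <- 7.5
  smc <- summarize_regions(const, res$atlas_r, subjects, component = 1L)
  expect_true(all(abs(smc$mean_gradient - 7.5) < 1e-12))
})

test_that("lr_ttest matches the textbook pooled formula and stats::t.test", {
  sm <- mk_summary(3, "b", 0, 0, sd = 0)
  sm$mean_gradient[sm$hemisphere == "L"] <- c(1, 2, 3)
  sm$mean_gradient[sm$hemisphere == "R"] <- c(4, 5, 6)
  res <- lr_ttest(sm, "b", "AS")
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)

  # identical sides: t = 0, p = 1 (including the zero-variance case)
  sm2 <- mk_summary(3, "b", 0, 0, sd = 0)
  res2 <- lr_ttest(sm2, "b", "AS")
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  # |t| grows when the separation between the side means widens at fixed
  # within-side spread
  sm3 <- sm
  right <- sm3$hemisphere == "R"
  sm3$mean_gradient[right] <- sm3$mean_gradient[right] + 2
  expect_gt(abs(lr_ttest(sm3, "b", "AS")$t), abs(res$t))

  # zero variance with unequal means is an error
  sm4 <- mk_summary(3, "b", 0, 0, sd = 0)
  sm4$mean_gradient[sm4$hemisphere == "L"] <- 1
  expect_error(lr_ttest(sm4, "b", "AS"), "zero")

  # Welch variant agrees with stats::t.test default
  res5 <- lr_ttest(sm, "b", "AS", welch = TRUE)
  tw <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res5$t, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(res5$p, tw$p.value, tolerance = 1e-12)
})

test_that("bh_adjust implements the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(2:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("asymmetry_table: counts, planted direction, null behaviour", {
  set.seed(12)
  bundles <- paste0("b", 1:20)
  means_l <- c(2, rep(0, 19))          # strong leftward shift in b1 only
  sm <- mk_summary(40, bundles, means_l, rep(0, 20), sd = 0.5)
  tab <- asymmetry_table(sm, run_config())
  expect_equal(nrow(tab), 60L)
  expect_setequal(unique(tab$cohort), c("AS", "MS", "FS"))
  b1 <- tab[tab$bundle == "b1", ]
  expect_true(all(b1$direction == "leftward"))
  expect_true(all(tab$q >= tab$p - 1e-15))

  # excluded bundles are dropped
  tab2 <- asymmetry_table(sm, run_config(excluded_bundles = "b1"))
  expect_equal(nrow(tab2), 57L)
  expect_false("b1" %in% tab2$bundle)

  # a midline-only structure never enters the table
  mid <- data.frame(subject_id = "s01", group = "M", bundle = "cc",
                    hemisphere = "midline", mean_gradient = 0,
                    voxel_count = 5L)
  sm3 <- rbind(sm, mid)
  class(sm3) <- c("region_summary", "data.frame")
  expect_false("cc" %in% asymmetry_table(sm3, run_config())$bundle)
})
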