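test_that("cell pair differences follow the inferior-minus-superior convention", {
  eye <- make_eye("S1", list(RETINA = const_matrix(50)))
  d <- cell_pair_differences(eye, "RETINA")
  expect_equal(nrow(d), 32L)
  expect_true(all(d$diff_um == 0))

  eye2 <- make_eye("S1", list(RNFL = hemi_matrix(46.33, 38.76)))
  d2 <- cell_pair_differences(eye2, "RNFL")
  expect_equal(d2$diff_um, rep(46.33 - 38.76, 32L))

  m <- const_matrix(50); m[2, 3] <- 60
  d3 <- cell_pair_differences(make_eye("S1", list(GCL = m)), "GCL")
  expect_equal(d3$diff_um[d3$inf_row == 2 & d3$inf_col == 3], 10)
  expect_equal(sum(d3$diff_um != 0), 1L)

  expect_error(cell_pair_differences(eye, "RNFL"), "no grid for layer RNFL")
})

test_that("paired t-test matches the closed formula and the reference implementation", {
  r <- paired_t_test(c(1, -1, 1, -1))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  d <- c(2, 4, 6, 8)
  r2 <- paired_t_test(d)
  expect_equal(r2$degrees_of_freedom, 3L)
  expect_equal(r2$t_statistic, mean(d) / (sd(d) / 2))
  ref <- t.test(d)  # one-sample t on differences == paired t
  expect_equal(r2$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(r2$t_statistic, 3.8729833, tolerance = 1e-7)
  expect_equal(r2$p_value, 0.03046629, tolerance = 1e-7)

  expect_error(paired_t_test(5), "at least 2")
  expect_error(paired_t_test(c(3, 3, 3)), "degenerate")
  expect_equal(paired_t_test(c(0, 0, 0))$p_value, 1)
  # sign(t) = sign(mean)
  expect_lt(paired_t_test(c(-2, -3, -1))$t_statistic, 0)
})

test_that("KS normality screen behaves as a sanity filter", {
  set.seed(5)
  x <- rnorm(1000, 30, 4)
  expect_gt(ks_normality(x)$p_value, 0.05)
  skewed <- exp(rnorm(1000))
  expect_lt(ks_normality(skewed)$p_value, 1e-6)
  expect_error(ks_normality(rep(1, 5)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("percentile range uses rank interpolation 1 + q(n-1) with inclusive bounds", {
  pr <- percentile_range(1:100)
  expect_equal(unname(pr["p2_5"]), 3.475)
  expect_equal(unname(pr["p97_5"]), 97.525)
  expect_equal(unname(percentile_range(rep(7, 10))), c(7, 7))
  # order property on random inputs
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(5:200, 1))
    pr <- percentile_range(x)
    expect_lte(pr["p2_5"], median(x))
    expect_gte(pr["p97_5"], median(x))
    expect_lte(pr["p2_5"], pr["p97_5"])
  }
  expect_error(percentile_range(1), "at least 2")
})

test_that("hemisphere summary pools cells and agrees with per-eye means", {
  co <- cohort(list(make_eye("A", list(GCL = hemi_matrix(30, 40))),
                    make_eye("B", list(GCL = hemi_matrix(34, 36)))))
  hs <- hemisphere_summary(co, "GCL")
  expect_equal(hs$pooled_mean[hs$hemisphere == "superior"], 38)
  expect_equal(hs$pooled_mean[hs$hemisphere == "inferior"], 32)
  pe <- attr(hs, "per_eye_means")
  expect_equal(dim(pe), c(2L, 2L))
  # pooled mean equals the mean of per-eye hemisphere means (equal weights)
  expect_equal(hs$pooled_mean, unname(colMeans(pe)))

  one <- cohort(list(make_eye("A", list(GCL = const_matrix(33)))))
  expect_equal(hemisphere_summary(one, "GCL")$pooled_sd, c(0, 0))

  co2 <- noisy_cohort(15, layer = "OPL", inf = 27.1, sup = 26.2, sd = 2,
                      seed = 3)
  hs2 <- hemisphere_summary(co2, "OPL")
  pe2 <- attr(hs2, "per_eye_means")
  expect_equal(hs2$pooled_mean[1], mean(pe2[, "inferior"]))
  expect_equal(hs2$pooled_mean[2], mean(pe2[, "superior"]))
})

test_that("pairwise summary table recovers constructed ground truth", {
  sym <- cohort(lapply(1:5, function(i) {
    make_eye(paste0("S", i), list(INL = const_matrix(30 + i)))
  }))
  tab <- pairwise_summary_table(sym, "INL")
  expect_equal(nrow(tab), 32L)
  expect_true(all(tab$mean_diff_um == 0))
  expect_true(all(!tab$significant))
  expect_true(all(tab$p == 1))

  # fixed +5 um inferior offset with noise: all pairs significant
  off <- noisy_cohort(60, layer = "INL", inf = 35, sup = 30, sd = 1.5,
                      seed = 21)
  tab2 <- pairwise_summary_table(off, "INL")
  expect_true(all(tab2$significant))
  expect_equal(mean(tab2$mean_diff_um), 5, tolerance = 0.2)
  expect_true(all(tab2$df == 59L))
  expect_true(all(tab2$p2_5_um <= tab2$p97_5_um))
})

test_that("reversing the sign convention negates effects but not p-values", {
  co <- noisy_cohort(25, layer = "IPL", inf = 26.8, sup = 27.8, sd = 2,
                     seed = 13)
  flipped <- cohort(lapply(co$eyes, function(e) {
    v <- e$grids$IPL$values[8:1, ]  # swap hemispheres
    make_eye(e$subject_id, list(IPL = v), e$laterality)
  }))
  a <- pairwise_summary_table(co, "IPL")
  b <- pairwise_summary_table(flipped, "IPL")
  expect_equal(b$mean_diff_um, -a$mean_diff_um)
  expect_equal(b$t, -a$t)
  expect_equal(b$p, a$p)
  expect_equal(b$p2_5_um, -a$p97_5_um)
  expect_equal(b$p97_5_um, -a$p2_5_um)
})

test_that("multiple-comparison adjustment only removes significances", {
  co <- noisy_cohort(30, layer = "RPE", inf = 12.8, sup = 12.6, sd = 0.8,
                     seed = 8)
  none <- pairwise_summary_table(co, "RPE", adjust = "none")
  holm <- pairwise_summary_table(co, "RPE", adjust = "holm")
  bh <- pairwise_summary_table(co, "RPE", adjust = "bh")
  expect_true(all(holm$significant <= none$significant))
  expect_true(all(bh$significant <= none$significant))
  expect_equal(holm$p, none$p)  # raw p-values are reported unchanged
})
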