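test_that("default calibration carries the reference hemisphere means for all layers", {
  cal <- default_calibration()
  expect_equal(nrow(cal), 10L)
  expect_setequal(cal$layer, layer_ids())
  expect_equal(cal$superior_mean[cal$layer == "ONL"], 55.54)
  expect_equal(cal$inferior_mean[cal$layer == "OUTER"], 77.00)
  expect_equal(cal$superior_mean[cal$layer == "RNFL"], 38.76)
  expect_equal(cal$inferior_mean[cal$layer == "RNFL"], 46.33)
  expect_true(all(cal$subject_sd >= 0 & cal$cell_sd >= 0 & cal$spatial_sd >= 0))
  # variance components never exceed the nonnegativity cap
  expect_true(all(cal$spatial_sd <= 0.35 * pmin(cal$superior_mean,
                                                cal$inferior_mean) + 1e-12))
})

test_that("the noiseless limit reproduces calibration means exactly", {
  cal <- default_calibration()
  cal$subject_sd <- 0; cal$cell_sd <- 0; cal$spatial_sd <- 0
  co <- generate_cohort(cohort_config(n_eyes = 3, calibration = cal, seed = 1))
  for (l in c("RNFL", "RPE")) {
    hs <- hemisphere_summary(co, l)
    expect_equal(hs$pooled_mean[hs$hemisphere == "superior"],
                 cal$superior_mean[cal$layer == l])
    expect_equal(hs$pooled_mean[hs$hemisphere == "inferior"],
                 cal$inferior_mean[cal$layer == l])
    expect_equal(hs$pooled_sd, c(0, 0))
  }
  # all eyes identical
  expect_equal(co$eyes[[1]]$grids$GCL$values, co$eyes[[3]]$grids$GCL$values)
})

test_that("generation is deterministic in the seed and leaves the caller's RNG alone", {
  cfg <- cohort_config(n_eyes = 6, seed = 123)
  set.seed(42); before <- runif(1)
  set.seed(42)
  a <- generate_cohort(cfg)
  after <- runif(1)
  expect_equal(before, after)  # RNG state restored
  b <- generate_cohort(cfg)
  expect_equal(a$eyes[[4]]$grids$INL$values, b$eyes[[4]]$grids$INL$values)
  expect_equal(vapply(a$eyes, function(e) e$laterality, ""),
               vapply(b$eyes, function(e) e$laterality, ""))
  c_ <- generate_cohort(cohort_config(n_eyes = 6, seed = 124))
  expect_false(identical(a$eyes[[1]]$grids$INL$values,
                         c_$eyes[[1]]$grids$INL$values))
})

test_that("laterality split matches right_fraction within rounding", {
  co <- generate_cohort(cohort_config(n_eyes = 300, seed = 2))
  lat <- vapply(co$eyes, function(e) e$laterality, "")
  expect_equal(sum(lat == "right"), round(0.51 * 300))
  co2 <- generate_cohort(cohort_config(n_eyes = 7, right_fraction = 1, seed = 2))
  expect_true(all(vapply(co2$eyes, function(e) e$laterality, "") == "right"))
})

test_that("the spatial gradient shifts cells but not hemisphere calibration", {
  cal <- default_calibration()
  cal$subject_sd <- 0; cal$cell_sd <- 0
  co <- generate_cohort(cohort_config(n_eyes = 2, calibration = cal, seed = 1))
  v <- co$eyes[[1]]$grids$RETINA$values
  expect_gt(stats::sd(as.vector(v[1:4, ])), 0)  # spatial structure present
  # zero-mean within each hemisphere: pooled means still exact
  expect_equal(mean(v[5:8, ]), cal$superior_mean[cal$layer == "RETINA"])
  expect_equal(mean(v[1:4, ]), cal$inferior_mean[cal$layer == "RETINA"])
  # midline-symmetric gradient: identical shape in both hemispheres
  expect_equal(unname(v[1:4, ]) - cal$inferior_mean[cal$layer == "RETINA"],
               unname(v[8:5, ]) - cal$superior_mean[cal$layer == "RETINA"])
})

test_that("pooled hemisphere means recover the calibration within 3 SE", {
  cfg <- cohort_config(n_eyes = 150, seed = 31)
  co <- generate_cohort(cfg)
  cal <- cfg$calibration
  for (l in c("GCL", "RETINA")) {
    i <- which(cal$layer == l)
    se <- sqrt(cal$subject_sd[i]^2 / 150 + cal$cell_sd[i]^2 / (150 * 32))
    hs <- hemisphere_summary(co, l)
    expect_lt(abs(hs$pooled_mean[hs$hemisphere == "superior"] -
                    cal$superior_mean[i]), 3 * se)
    expect_lt(abs(hs$pooled_mean[hs$hemisphere == "inferior"] -
                    cal$inferior_mean[i]), 3 * se)
  }
})

test_that("lesion injection honours counts, ground truth and the zero-delta identity", {
  cells <- expand.grid(row = 5:6, col = 4:6)
  cfg <- cohort_config(n_eyes = 40, seed = 9)
  clean <- generate_cohort(cfg)

  les0 <- inject_lesions(clean, lesion_spec("GCL", cells, 0, 0.5), seed = 4)
  expect_equal(les0$cohort$eyes[[7]]$grids$GCL$values,
               clean$eyes[[7]]$grids$GCL$values)

  les <- inject_lesions(clean, lesion_spec("GCL", cells, -40, 0.1), seed = 4)
  expect_equal(length(unique(les$labels$subject_id)), round(0.1 * 40))
  expect_equal(nrow(les$labels), 4L * nrow(cells))
  affected <- unique(les$labels$subject_id)
  ids <- vapply(clean$eyes, function(e) e$subject_id, "")
  for (sid in affected) {
    i <- match(sid, ids)
    delta <- les$cohort$eyes[[i]]$grids$GCL$values -
      clean$eyes[[i]]$grids$GCL$values
    expect_equal(sum(delta != 0), nrow(cells))
    # -40 um thinning, floored at zero thickness where GCL is thinner than 40
    v0 <- clean$eyes[[i]]$grids$GCL$values[cbind(cells$row, cells$col)]
    expect_equal(delta[cbind(cells$row, cells$col)], pmax(v0 - 40, 0) - v0)
    # untouched layers identical
    expect_equal(les$cohort$eyes[[i]]$grids$RNFL$values,
                 clean$eyes[[i]]$grids$RNFL$values)
  }
  # unaffected eyes untouched
  un <- setdiff(ids, affected)[1]
  expect_equal(les$cohort$eyes[[match(un, ids)]]$grids$GCL$values,
               clean$eyes[[match(un, ids)]]$grids$GCL$values)

  # lesions requested through the config attach ground-truth labels
  cfg_l <- cohort_config(n_eyes = 40, seed = 9,
                         lesions = lesion_spec("GCL", cells, -40, 0.1))
  with_l <- generate_cohort(cfg_l)
  expect_false(is.null(attr(with_l, "lesion_labels")))
  # base thicknesses of unaffected eyes are not perturbed by lesion draws
  aff2 <- unique(attr(with_l, "lesion_labels")$subject_id)
  un2 <- setdiff(ids, aff2)[1]
  expect_equal(with_l$eyes[[match(un2, ids)]]$grids$GCL$values,
               clean$eyes[[match(un2, ids)]]$grids$GCL$values)

  bad <- data.frame(row = 9, col = 1)
  expect_error(lesion_spec("GCL", bad, -40, 0.1), "invalid cell address")
})

test_that("a null (zero-offset) layer shows ~alpha significant pairs", {
  cal <- default_calibration()[default_calibration()$layer == "GCL", ]
  cal$inferior_mean <- cal$superior_mean  # no hemisphere offset
  rates <- vapply(1:40, function(r) {
    co <- generate_cohort(cohort_config(n_eyes = 20, calibration = cal,
                                        seed = 5000 + r))
    mean(pairwise_summary_table(co, "GCL")$significant)
  }, 1)
  rate <- mean(rates)  # 40 x 32 = 1280 independent null tests
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 1280))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1280))
})

test_that("cohort configs load from JSON files including lesions", {
  cfgfile <- file.path(tempdir(), "config.json")
  jsonlite::write_json(list(
    n_eyes = 10, right_fraction = 0.5, seed = 77,
    spatial_profile = "flat",
    lesions = list(list(layer = "GCL", delta_um = -40,
                        affected_fraction = 0.2,
                        cells = list(list(row = 5, col = 4),
                                     list(row = 5, col = 5))))),
    cfgfile, auto_unbox = TRUE, digits = NA)
  cfg <- cohort_config_from_file(cfgfile)
  expect_equal(cfg$n_eyes, 10L)
  expect_equal(cfg$spatial_profile, "flat")
  expect_equal(length(cfg$lesions), 1L)
  expect_equal(nrow(cfg$lesions[[1]]$cells), 2L)
  expect_equal(cfg$lesions[[1]]$delta_um, -40)
  co <- generate_cohort(cfg)
  expect_equal(length(co$eyes), 10L)
  expect_equal(length(unique(attr(co, "lesion_labels")$subject_id)), 2L)
})
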