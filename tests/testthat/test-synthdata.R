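test_that("plain nodules are solid connected blobs with Betti numbers (1,0,0)", {
  scan <- generate_nodule(nodule_params(base_radius_mm = 7), seed = 2)
  expect_s3_class(scan$volume, "image_volume")
  expect_s3_class(scan$mask, "seg_mask")
  expect_equal(unname(betti_numbers(scan$mask)), c(1L, 0L, 0L))
})

test_that("planted cavities are recovered exactly by the labeling oracle", {
  for (k in 1:2) {
    scan <- generate_nodule(nodule_params(base_radius_mm = 10, cavity_count = k),
                            seed = 10 + k)
    expect_equal(unname(betti_numbers(scan$mask)), c(1L, 0L, k))
  }
})

test_that("generation is a pure function of params and seed", {
  p <- nodule_params(base_radius_mm = 8, lobulation_count = 2,
                     cavity_count = 1, spicule_count = 2)
  a <- generate_nodule(p, seed = 7)
  b <- generate_nodule(p, seed = 7)
  expect_identical(unclass(a$volume), unclass(b$volume))
  expect_identical(unclass(a$mask), unclass(b$mask))
  c <- generate_nodule(p, seed = 8)
  expect_false(identical(unclass(a$volume), unclass(c$volume)))
})

test_that("a nodule that cannot fit the requested grid raises a sizing error", {
  expect_error(generate_nodule(nodule_params(base_radius_mm = 10),
                               grid_shape = c(12, 12, 6), seed = 1),
               "does not fit")
})

test_that("cohorts honor patient counts, class balance and score range", {
  # small radii keep this cohort cheap; the class structure is what is tested
  cfg <- effect_config(
    A = list(radius = c(mean = 5, sd = 0.3), lobulation = c(base = 0, lambda = 0),
             cavities = c(base = 0, p_extra = 0), spicules = c(base = 0, lambda = 0),
             mu = c(mean = 30, sd = 5)),
    B = list(radius = c(mean = 5.5, sd = 0.3), lobulation = c(base = 0, lambda = 0),
             cavities = c(base = 0, p_extra = 0), spicules = c(base = 0, lambda = 0),
             mu = c(mean = 45, sd = 5)))
  co <- generate_cohort(20, multi_nodule_rate = 0, config = cfg, seed = 3)
  expect_equal(nrow(co), 20L)
  expect_equal(unname(table(co$class_label)["A"]), 10L)
  expect_false(anyDuplicated(co$nodule_id) > 0)
  expect_true(all(co$malignancy_score >= 1 & co$malignancy_score <= 5))
})

test_that("multi-nodule patients occur at the configured Bernoulli rate", {
  cfg <- effect_config(
    A = list(radius = c(mean = 5, sd = 0.2), lobulation = c(base = 0, lambda = 0),
             cavities = c(base = 0, p_extra = 0), spicules = c(base = 0, lambda = 0),
             mu = c(mean = 30, sd = 5)))
  cfg$B <- cfg$A
  co <- generate_cohort(100, multi_nodule_rate = 0.2, config = cfg, seed = 5)
  extra <- nrow(co) - 100
  # 99% binomial interval for Binomial(100, 0.2)
  expect_gte(extra, qbinom(0.005, 100, 0.2))
  expect_lte(extra, qbinom(0.995, 100, 0.2))
  # multi-nodule patients share their patient id across rows
  expect_gt(length(unique(co$patient_id)), 1)
  expect_equal(length(unique(co$patient_id)), 100L)
})

test_that("degenerate class proportions are flagged", {
  expect_warning(
    generate_cohort(4, class_proportions = c(A = 1, B = 0),
                    multi_nodule_rate = 0, seed = 1,
                    config = effect_config(
                      A = list(radius = c(mean = 5, sd = 0.1),
                               lobulation = c(base = 0, lambda = 0),
                               cavities = c(base = 0, p_extra = 0),
                               spicules = c(base = 0, lambda = 0),
                               mu = c(mean = 30, sd = 2)))),
    "degenerate")
})

test_that("stand-in radiomic features obey their contracts", {
  msk <- make_ball_mask(5)
  vol <- make_const_volume(msk, 40)
  f <- standin_radiomic_features(vol, msk)
  expect_equal(unname(f["intensity_sd"]), 0)
  expect_equal(unname(f["intensity_mean"]), 40)

  # doubling intensities doubles location features, leaves shape untouched
  v2 <- image_volume(unclass(vol) * 2, voxel_spacing(vol))
  f2 <- standin_radiomic_features(v2, msk)
  for (nm in c("intensity_mean", "intensity_min", "intensity_max",
               "intensity_median", "intensity_p10", "intensity_p90"))
    expect_equal(unname(f2[nm]), 2 * unname(f[nm]))
  shape_nms <- grep("^shape_", names(f), value = TRUE)
  expect_equal(f2[shape_nms], f[shape_nms])

  # a ball is more spherical than an elongated ellipsoid of equal volume
  ell <- local({
    shape <- c(41L, 17L, 17L)
    xs <- seq_len(shape[1]) - 21; ys <- seq_len(shape[2]) - 9
    zs <- seq_len(shape[3]) - 9
    d2 <- outer(outer((xs / 16)^2, (ys / 5)^2, `+`), (zs / 5)^2, `+`)
    seg_mask(d2 <= 1, c(1, 1, 1))
  })
  fb <- standin_radiomic_features(make_const_volume(msk), msk)
  fe <- standin_radiomic_features(make_const_volume(ell), ell)
  expect_gt(fb["shape_sphericity"], fe["shape_sphericity"])

  expect_error(standin_radiomic_features(vol,
    seg_mask(array(c(0, rep(0, 26)), c(3, 3, 3)) + 0, c(1, 1, 1))),
    "foreground")
})

test_that("the malignancy score tracks planted morphology", {
  co <- fixture("cohort_small", function()
    generate_cohort(12, multi_nodule_rate = 0, seed = 21))
  a <- co$malignancy_score[co$class_label == "A"]
  b <- co$malignancy_score[co$class_label == "B"]
  expect_gt(mean(b), mean(a))
})
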