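test_that("stratified folds balance classes and grouped folds keep patients whole", {
  tbl <- tibble::tibble(nodule_id = paste0("N", 1:10),
                        patient_id = paste0("P", 1:10),
                        class_label = rep(c("A", "B"), 5))
  fa <- make_folds(tbl, folds = 5, repeats = 3, sampling = "stratified_nodule",
                   seed = 1)
  per <- dplyr::count(dplyr::left_join(fa, tbl, by = "nodule_id"),
                      repeat_id, fold, class_label)
  expect_true(all(per$n == 1))

  tbl2 <- tibble::tibble(nodule_id = paste0("N", 1:12),
                         patient_id = c(rep("P1", 3), paste0("P", 2:10)),
                         class_label = rep(c("A", "B"), 6))
  for (sampling in c("grouped_patient_random", "grouped_patient_stratified")) {
    fg <- make_folds(tbl2, folds = 3, repeats = 4, sampling = sampling,
                     seed = 2)
    p1 <- dplyr::left_join(fg, tbl2, by = "nodule_id") |>
      dplyr::filter(patient_id == "P1") |>
      dplyr::group_by(repeat_id) |>
      dplyr::summarise(k = dplyr::n_distinct(fold))
    expect_true(all(p1$k == 1))
  }
})

test_that("fold assignments are reproducible and vary across repeats", {
  tbl <- tibble::tibble(nodule_id = paste0("N", 1:20),
                        patient_id = paste0("P", 1:20),
                        class_label = rep(c("A", "B"), 10))
  f1 <- make_folds(tbl, repeats = 10, seed = 7)
  f2 <- make_folds(tbl, repeats = 10, seed = 7)
  expect_identical(f1, f2)
  wide <- tidyr::pivot_wider(f1, names_from = repeat_id, values_from = fold)
  expect_gt(length(unique(apply(wide[-1], 2, paste, collapse = ""))), 5)
})

test_that("degenerate fold requests error out", {
  tbl <- tibble::tibble(nodule_id = paste0("N", 1:6),
                        patient_id = paste0("P", 1:6),
                        class_label = c(rep("A", 4), "B", "B"))
  expect_error(make_folds(tbl, folds = 5), "fewer than 5 folds")
  expect_error(make_folds(tbl[1:4, ], folds = 3), "both classes")
})

test_that("roc_auc matches hand values, tie convention and exhaustive pair counting", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(0.3, 0.3), c(1, 0)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_message(expect_true(is.na(roc_auc(c(0.1, 0.2), c(1, 1)))),
                 "one class")

  pair_count_auc <- function(s, l) {
    pos <- which(l == 1); neg <- which(l == 0); tot <- 0
    for (i in pos) for (j in neg)
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(12, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      l <- sample(c(0, 1), n, TRUE)
      if (length(unique(l)) < 2) next
      s <- round(runif(n), 1)  # coarse scores force ties
      expect_equal(roc_auc(s, l), pair_count_auc(s, l))
    }
  })
})

test_that("r_squared matches its closed form", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(r_squared(rep(2, 3), c(1, 2, 3)), 0.0)
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_message(expect_true(is.na(r_squared(c(1, 2), c(3, 3)))), "constant")
})

test_that("compare_strategies handles identical, dominating and noisy scores", {
  x <- c(0.7, 0.8, 0.6, 0.75, 0.8)
  expect_gte(as.numeric(compare_strategies(x, x)), 0.5)
  p_dom <- compare_strategies(x, x + 0.1)
  expect_lt(as.numeric(p_dom), 1e-10)
  expect_true(attr(p_dom, "degenerate"))
  withr::with_seed(13, {
    a <- runif(20, 0.4, 0.6); b <- a + rnorm(20, 0.15, 0.02)
  })
  expect_lt(as.numeric(compare_strategies(a, b)), 0.05)
  expect_gt(as.numeric(compare_strategies(b, a)), 0.5)
  expect_lt(as.numeric(compare_strategies(a, b, method = "wilcoxon")), 0.05)
  expect_error(compare_strategies(1:3, 1:4), "mismatched")
})

test_that("experiments produce a full, reproducible score grid", {
  ft <- make_feature_table(n = 30, signal = 2, seed = 14)
  r1 <- run_experiment(ft, kinds = "LR", strategies = c("rad", "top", "vote"),
                       repeats = 2, folds = 3, seed = 5)
  expect_equal(nrow(r1$scores), 3L * 2L * 3L)
  expect_true(all(table(r1$scores$strategy) == 6))
  expect_true(all(r1$scores$score >= 0 & r1$scores$score <= 1, na.rm = TRUE))
  r2 <- run_experiment(ft, kinds = "LR", strategies = c("rad", "top", "vote"),
                       repeats = 2, folds = 3, seed = 5)
  expect_identical(r1$scores, r2$scores)
  expect_identical(glance(r1), glance(r2))
  expect_s3_class(tidy(r1), "tbl_df")
})

test_that("regression experiments score r-squared on the malignancy outcome", {
  ft <- make_feature_table(n = 36, signal = 2, seed = 15)
  r <- run_experiment(ft, outcome_col = "malignancy_score", kinds = "LR",
                      strategies = c("rad", "vote"), repeats = 2, folds = 3,
                      sampling = "grouped_patient_random", seed = 6)
  expect_equal(r$config$task, "regression")
  expect_true(all(r$scores$score <= 1, na.rm = TRUE))
  expect_equal(nrow(r$comparisons), 1L)
})

test_that("stacking skips are recorded in the log, not fatal", {
  ft <- make_feature_table(n = 24, signal = 1, seed = 16)
  ft$class_label <- c(rep("B", 6), rep("A", 18))  # minority too small to stack
  r <- run_experiment(ft, kinds = "LR", strategies = c("rad", "stack"),
                      repeats = 1, folds = 3, seed = 7)
  expect_true(any(is.na(r$scores$score[r$scores$strategy == "stack"])))
  expect_gt(nrow(r$log), 0)
  expect_true(any(grepl("stacking", r$log$event)))
})
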