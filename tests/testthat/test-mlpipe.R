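test_that("preprocessing scales, imputes, clips and bins as specified", {
  tr <- tibble::tibble(a = c(0, 5, 10), b = c(3, 5, NA))
  st <- fit_preprocess(tr)
  out <- apply_preprocess(st, tr)
  expect_equal(out$continuous$a, c(0, 0.5, 1))
  # NA imputed with the training mean (4) before scaling: (4-3)/(5-3)
  expect_equal(out$continuous$b, c(0, 1, 0.5))
  expect_equal(out$binned$a, c(1, 3, 5))
  expect_equal(st$n_bins, 5L)

  te <- tibble::tibble(a = c(-2, 12, 7), b = c(4, 4, 4))
  oute <- apply_preprocess(st, te)
  expect_equal(oute$continuous$a, c(0, 1, 0.7))  # clipped to [0, 1]
  expect_true(all(oute$binned$a %in% 1:5))
})

test_that("constant and all-missing features are handled with warnings", {
  tr <- tibble::tibble(a = c(1, 1, 1), b = c(NA_real_, NA, NA), c = 1:3)
  expect_warning(expect_warning(st <- fit_preprocess(tr), "no observed"),
                 "constant")
  out <- apply_preprocess(st, tr)
  expect_false("b" %in% names(out$continuous))
  expect_equal(out$continuous$a, c(0, 0, 0))
})

test_that("mRMR picks a perfect predictor first and returns k names", {
  withr::with_seed(2, {
    n <- 60
    y <- factor(rep(c("A", "B"), n / 2))
    X <- tibble::tibble(
      noise1 = sample(1:5, n, TRUE), noise2 = sample(1:5, n, TRUE),
      signal = as.integer(y), noise3 = sample(1:5, n, TRUE))
  })
  sel <- mrmr_select(X, y, k = 2)
  expect_equal(sel[1], "signal")
  expect_length(sel, 2L)
  expect_length(mrmr_select(X, y, k = 99), 4L)
  expect_error(mrmr_select(X, y, k = 0), "at least 1")
})

test_that("a duplicate of a selected feature is penalized by redundancy", {
  withr::with_seed(3, {
    n <- 80
    y <- factor(rep(c("A", "B"), n / 2))
    strong <- as.integer(y) + sample(0:1, n, TRUE)
    weak <- ifelse(runif(n) < 0.75, as.integer(y), sample(1:2, n, TRUE))
    X <- tibble::tibble(strong = strong, strong_copy = strong, weak = weak)
  })
  sel <- mrmr_select(X, y, k = 3)
  expect_equal(sel[1], "strong")
  expect_equal(sel[2], "weak")  # the exact copy cannot come before new signal
})

test_that("mRMR agrees with an exhaustive greedy oracle on random instances", {
  # oracle: direct table()-based MI and a literal greedy loop
  mi_tab <- function(x, y) {
    p <- table(x, y) / length(x)
    px <- rowSums(p); py <- colSums(p); i <- p > 0
    sum(p[i] * log(p[i] / outer(px, py)[i]))
  }
  greedy_oracle <- function(X, y, k) {
    feats <- names(X); sel <- character(0)
    for (s in seq_len(min(k, length(feats)))) {
      cand <- setdiff(feats, sel)
      sc <- vapply(cand, function(f) {
        r <- mi_tab(X[[f]], y)
        if (length(sel)) r - mean(vapply(sel, function(g)
          mi_tab(X[[f]], X[[g]]), numeric(1))) else r
      }, numeric(1))
      sel <- c(sel, cand[order(-sc, cand)][1])
    }
    sel
  }
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- sample(20:60, 1); p <- sample(3:6, 1)
      y <- factor(sample(c("A", "B"), n, TRUE))
      X <- tibble::as_tibble(setNames(
        lapply(seq_len(p), function(j)
          sample(1:5, n, TRUE, prob = runif(5))), paste0("f", seq_len(p))))
      X$f1 <- pmin(5L, as.integer(y) + sample(0:2, n, TRUE))
      k <- sample(2:p, 1)
      expect_identical(mrmr_select(X, y, k = k), greedy_oracle(X, y, k))
    }
  })
})

test_that("every model family separates a linearly separable toy problem", {
  withr::with_seed(4, {
    n <- 60
    y <- factor(rep(c("A", "B"), each = n / 2))
    X <- tibble::tibble(x1 = rnorm(n) + 3 * (y == "B"), x2 = rnorm(n))
  })
  for (kind in c("LR", "RF", "KNN", "SV", "BAY", "XGB")) {
    sc <- train_predict(kind, X, y, X, seed = 1)
    expect_gt(roc_auc(sc, y), 0.95)
  }
})

test_that("KNN with k = 1 memorizes its training set", {
  withr::with_seed(6, {
    X <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20))
    y <- factor(sample(c("A", "B"), 20, TRUE))
  })
  sc <- train_predict("KNN", X, y, X, knn_k = 1)
  expect_equal(sc, as.numeric(y == "B"))
  yr <- rnorm(20)
  expect_equal(train_predict("KNN", X, yr, X, knn_k = 1), yr)
})

test_that("stochastic learners are deterministic given the seed", {
  withr::with_seed(5, {
    n <- 40
    y <- factor(sample(c("A", "B"), n, TRUE))
    X <- tibble::as_tibble(matrix(rnorm(n * 4), n,
                                  dimnames = list(NULL, paste0("x", 1:4))))
    Xt <- tibble::as_tibble(matrix(rnorm(20 * 4), 20,
                                   dimnames = list(NULL, paste0("x", 1:4))))
  })
  for (kind in c("RF", "SV", "XGB")) {
    expect_identical(train_predict(kind, X, y, Xt, seed = 42),
                     train_predict(kind, X, y, Xt, seed = 42))
  }
  ys <- rnorm(40)
  for (kind in c("RF", "SV", "XGB", "BAY")) {
    expect_identical(train_predict(kind, X, ys, Xt, seed = 42),
                     train_predict(kind, X, ys, Xt, seed = 42))
  }
})

test_that("single-class training folds raise the dedicated condition", {
  X <- tibble::tibble(x = rnorm(10))
  expect_error(train_predict("LR", X, factor(rep("A", 10)), X),
               class = "topohist_fold_error")
})

test_that("soft voting averages the block scores and collapses for duplicated blocks", {
  ft <- make_feature_table(n = 40, signal = 2, seed = 8)
  tr <- ft[1:30, ]; te <- ft[31:40, ]
  r <- combine_blocks("rad", "LR", tr, te, "class_label")
  t <- combine_blocks("top", "LR", tr, te, "class_label")
  v <- combine_blocks("vote", "LR", tr, te, "class_label")
  expect_equal(v, (r + t) / 2)

  # identical blocks: vote equals the single-block model
  dup <- ft[, !grepl("^top_", names(ft))]
  for (nm in grep("^rad_", names(ft), value = TRUE))
    dup[[sub("rad_", "top_", nm)]] <- ft[[nm]]
  v2 <- combine_blocks("vote", "LR", dup[1:30, ], dup[31:40, ], "class_label")
  r2 <- combine_blocks("rad", "LR", dup[1:30, ], dup[31:40, ], "class_label")
  expect_equal(v2, r2, tolerance = 1e-10)
})

test_that("stacking learns from informative base outputs and skips tiny classes", {
  ft <- make_feature_table(n = 60, signal = 3, seed = 9)
  tr <- ft[1:44, ]; te <- ft[45:60, ]
  sc <- combine_blocks("stack", "LR", tr, te, "class_label", seed = 2)
  expect_equal(roc_auc(sc, te$class_label), 1.0)

  tiny <- ft[c(1:20, which(ft$class_label == "B")[1:3]), ]
  tiny$class_label <- c(rep("A", 20), rep("B", 3))
  expect_error(
    combine_blocks("stack", "LR", tiny, te, "class_label"),
    class = "topohist_stack_skip")
})

test_that("concat pools blocks before selection but still returns one model's scores", {
  ft <- make_feature_table(n = 40, signal = 2, seed = 10)
  sc <- combine_blocks("concat", "LR", ft[1:30, ], ft[31:40, ], "class_label")
  expect_length(sc, 10L)
  expect_true(all(sc >= 0 & sc <= 1))
})
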