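#' Fit the shared feature preprocessing
#'
#' Learns, on training rows only: per-feature imputation means, min-max
#' ranges for scaling to `[0, 1]`, and the implied 5 equal-width bins on
#' `[0, 1]` used by the downstream feature selection. Features that are
#' entirely missing on the training rows are dropped with a warning;
#' constant features are flagged (they scale to 0).
#'
#' @param train data frame of numeric feature columns (training rows only).
#' @return a `preprocess_state` list.
#' @export
fit_preprocess <- function(train) {
  train <- as.data.frame(train)
  stopifnot(nrow(train) >= 2)
  all_na <- vapply(train, function(x) all(is.na(x)), logical(1))
  if (any(all_na)) {
    warning("dropping feature(s) with no observed training values: ",
            paste(names(train)[all_na], collapse = ", "))
    train <- train[, !all_na, drop = FALSE]
  }
  means <- vapply(train, function(x) mean(x, na.rm = TRUE), numeric(1))
  mins <- vapply(train, function(x) min(x, na.rm = TRUE), numeric(1))
  maxs <- vapply(train, function(x) max(x, na.rm = TRUE), numeric(1))
  if (any(maxs == mins))
    warning("constant training feature(s) scaled to 0: ",
            paste(names(train)[maxs == mins], collapse = ", "))
  structure(list(features = names(train), means = means, mins = mins,
                 maxs = maxs, n_bins = 5L),
            class = "preprocess_state")
}

#' Apply a fitted preprocessing state
#'
#' Imputes missing values with the training means, min-max scales with the
#' training ranges (values outside the training range are clipped to
#' `[0, 1]`; constant features map to 0), and bins the scaled values into 5
#' equal-width partitions of `[0, 1]`.
#'
#' @param state a `preprocess_state` from [fit_preprocess()].
#' @param rows data frame containing at least the state's features.
#' @return list with `continuous` (scaled tibble) and `binned` (integer
#'   bins 1-5).
#' @export
apply_preprocess <- function(state, rows) {
  rows <- as.data.frame(rows)[, state$features, drop = FALSE]
  cont <- purrr::imap(rows, function(x, nm) {
    x[is.na(x)] <- state$means[[nm]]
    rng <- state$maxs[[nm]] - state$mins[[nm]]
    if (rng == 0) return(rep(0, length(x)))
    pmin(1, pmax(0, (x - state$mins[[nm]]) / rng))
  }) |> tibble::as_tibble()
  binned <- dplyr::mutate(cont, dplyr::across(
    dplyr::everything(), ~ pmin(state$n_bins, floor(.x * state$n_bins) + 1L)))
  list(continuous = cont, binned = binned)
}

mi_discrete <- function(x, y) {
  xi <- as.integer(factor(x)); yi <- as.integer(factor(y))
  mi_codes(xi, max(xi), yi, max(yi))
}

# empirical MI from integer codes in 1..nx / 1..ny, via a tabulated joint
mi_codes <- function(xi, nx, yi, ny) {
  n <- length(xi)
  j <- tabulate((xi - 1L) * ny + yi, nx * ny) / n
  px <- tabulate(xi, nx) / n
  py <- tabulate(yi, ny) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ent(px) + ent(py) - ent(j)
}

discretize_outcome <- function(y, n_bins = 5L) {
  if (is.numeric(y)) {
    br <- unique(quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) return(factor(rep(1, length(y))))
    cut(y, breaks = br, include.lowest = TRUE, labels = FALSE)
  } else factor(y)
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection over discretized features: the first feature
#' maximizes the empirical mutual information with the outcome; each
#' subsequent feature maximizes relevance minus the mean mutual information
#' with the already selected set (MID criterion; `"MIQ"` uses the quotient).
#' Continuous outcomes are discretized into 5 equal-frequency bins first.
#' Ties break lexicographically on the feature name, so selection is
#' deterministic.
#'
#' @param binned data frame of discretized (binned) features.
#' @param outcome binary factor/vector, or numeric for regression problems.
#' @param k number of features to select (default 10).
#' @param criterion `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return character vector of `min(k, p)` feature names in selection order.
#' @export
mrmr_select <- function(binned, outcome, k = 10, criterion = c("MID", "MIQ")) {
  criterion <- match.arg(criterion)
  if (k < 1) stop("`k` must be at least 1")
  binned <- as.data.frame(binned)
  y <- discretize_outcome(outcome)
  yi <- as.integer(factor(y)); ny <- max(yi)
  feats <- names(binned)
  xm <- vapply(binned, function(x) as.integer(x), integer(nrow(binned)))
  if (is.null(dim(xm))) xm <- matrix(xm, nrow = nrow(binned))
  if (anyNA(xm) || min(xm) < 1L)
    xm <- apply(xm, 2, function(x) as.integer(factor(x)))
  nb <- max(xm)
  rel <- setNames(vapply(seq_along(feats), function(f)
    mi_codes(xm[, f], nb, yi, ny), numeric(1)), feats)
  k <- min(k, length(feats))
  selected <- character(0)
  red_sum <- setNames(numeric(length(feats)), feats)
  for (step in seq_len(k)) {
    cand <- setdiff(feats, selected)
    score <- if (step == 1) rel[cand] else {
      red <- red_sum[cand] / length(selected)
      if (criterion == "MID") rel[cand] - red
      else rel[cand] / (red + .Machine$double.eps)
    }
    pick <- cand[order(-score, cand)][1]
    selected <- c(selected, pick)
    if (step < k) {
      rest <- setdiff(feats, selected)
      pk <- xm[, match(pick, feats)]
      red_sum[rest] <- red_sum[rest] + vapply(
        match(rest, feats), function(f) mi_codes(xm[, f], nb, pk, nb),
        numeric(1))
    }
  }
  selected
}

# ---------------------------------------------------------------------------

#' Train one model family and score a test set
#'
#' The six model families of the benchmark, each with a classification and a
#' regression variant: logistic/linear regression (`LR`), random forest
#' (`RF`, ranger), k-nearest neighbors (`KNN`), support vector machine
#' (`SV`, e1071), Gaussian naive Bayes / ridge regression with a Gaussian
#' prior (`BAY`), and extreme gradient-boosted trees (`XGB`). Classification
#' variants return the probability of the positive class (the second factor
#' level); regression variants return real predictions. Stochastic learners
#' run single-threaded with fixed seeds, so identical inputs give identical
#' outputs.
#'
#' @param kind one of `"LR"`, `"RF"`, `"KNN"`, `"SV"`, `"BAY"`, `"XGB"`.
#' @param train_x,test_x data frames of (preprocessed, selected) features.
#' @param train_y outcome: a two-level factor for classification, numeric
#'   for regression.
#' @param task `"classification"` or `"regression"` (inferred from
#'   `train_y` when `NULL`).
#' @param seed integer seed for stochastic learners.
#' @param knn_k neighbor count for the KNN variants (capped at the training
#'   size).
#' @return numeric vector of test scores (probabilities or predictions).
#' @export
train_predict <- function(kind, train_x, train_y, test_x, task = NULL,
                          seed = 1, knn_k = 5) {
  kind <- match.arg(kind, c("LR", "RF", "KNN", "SV", "BAY", "XGB"))
  train_x <- as.data.frame(train_x)
  test_x <- as.data.frame(test_x)[, names(train_x), drop = FALSE]
  if (is.null(task))
    task <- if (is.numeric(train_y)) "regression" else "classification"
  if (task == "classification") {
    train_y <- factor(train_y)
    if (nlevels(train_y) < 2)
      rlang::abort("single-class training fold", class = "topohist_fold_error")
    positive <- levels(train_y)[2]
  }
  xm_tr <- as.matrix(train_x)
  xm_te <- as.matrix(test_x)
  if (task == "classification") {
    switch(kind,
      LR = {
        df <- cbind(.y = as.integer(train_y == positive), train_x)
        fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
        unname(suppressWarnings(predict(fit, newdata = test_x,
                                        type = "response")))
      },
      RF = {
        fit <- ranger::ranger(x = train_x, y = train_y, probability = TRUE,
                              seed = seed, num.threads = 1)
        unname(predict(fit, data = test_x,
                       num.threads = 1)$predictions[, positive])
      },
      KNN = {
        kk <- min(knn_k, nrow(train_x))
        pred <- with_seed(seed,
          class::knn(xm_tr, xm_te, cl = train_y, k = kk, prob = TRUE))
        pw <- attr(pred, "prob")
        ifelse(pred == positive, pw, 1 - pw)
      },
      SV = {
        fit <- with_seed(seed, suppressWarnings(
          e1071::svm(x = xm_tr, y = train_y, probability = TRUE)))
        pr <- attr(predict(fit, xm_te, probability = TRUE), "probabilities")
        unname(pr[, positive])
      },
      BAY = {
        fit <- e1071::naiveBayes(x = train_x, y = train_y)
        unname(predict(fit, test_x, type = "raw")[, positive])
      },
      XGB = {
        lab <- as.numeric(train_y == positive)
        fit <- xgb_fit(xm_tr, lab, "binary:logistic", seed)
        xgb_score(fit, xm_te)
      })
  } else {
    switch(kind,
      LR = {
        df <- cbind(.y = train_y, train_x)
        fit <- suppressWarnings(lm(.y ~ ., data = df))
        unname(suppressWarnings(predict(fit, newdata = test_x)))
      },
      RF = {
        fit <- ranger::ranger(x = train_x, y = train_y, seed = seed,
                              num.threads = 1)
        unname(predict(fit, data = test_x, num.threads = 1)$predictions)
      },
      KNN = {
        kk <- min(knn_k, nrow(train_x))
        fit <- caret::knnreg(xm_tr, train_y, k = kk)
        unname(predict(fit, xm_te))
      },
      SV = {
        fit <- with_seed(seed, suppressWarnings(
          e1071::svm(x = xm_tr, y = train_y)))
        unname(predict(fit, xm_te))
      },
      BAY = ridge_predict(xm_tr, train_y, xm_te, lambda = 1),
      XGB = {
        fit <- xgb_fit(xm_tr, train_y, "reg:squarederror", seed)
        xgb_score(fit, xm_te)
      })
  }
}

# ridge regression with a fixed Gaussian prior on standardized coefficients:
# the MAP estimate of Bayesian linear regression with known scales
ridge_predict <- function(x, y, newx, lambda = 1) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, `/`)
  ym <- mean(y)
  beta <- solve(crossprod(xs) + lambda * diag(ncol(xs)),
                crossprod(xs, y - ym))
  xt <- sweep(sweep(newx, 2, mu), 2, s, `/`)
  drop(xt %*% beta) + ym
}

xgb_fit <- function(x, y, objective, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  params <- list(objective = objective, nthread = 1, eta = 0.3, max_depth = 6,
                 seed = seed)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = 50,
                     verbose = 0)
}

xgb_score <- function(fit, x) {
  unname(predict(fit, xgboost::xgb.DMatrix(x)))
}

# ---------------------------------------------------------------------------

block_columns <- function(df, prefix) {
  nms <- grep(paste0("^", prefix), names(df), value = TRUE)
  if (!length(nms)) stop("no feature columns with prefix '", prefix, "'")
  nms
}

# the single-block pipeline: fold-local preprocessing, mRMR on the binned
# copies, model trained on the continuous copies of the selected features
block_scores <- function(cols, kind, train, test, y_tr, task, k, seed) {
  state <- fit_preprocess(train[, cols, drop = FALSE])
  tr <- apply_preprocess(state, train)
  te <- apply_preprocess(state, test)
  sel <- mrmr_select(tr$binned, y_tr, k = k)
  train_predict(kind, tr$continuous[, sel, drop = FALSE], y_tr,
                te$continuous[, sel, drop = FALSE], task = task, seed = seed)
}

#' Combine feature blocks under one strategy
#'
#' Runs the full fold pipeline (preprocess, mRMR selection, model) for one
#' combination strategy: `rad` and `top` use a single block; `concat` pools
#' both blocks before selection (still `k` features); `vote` averages the
#' two single-block models' probabilities (or predictions); `stack` trains
#' base models per block, produces out-of-fold outputs on the training rows
#' through an internal seeded 5-fold split, fits a final model of the same
#' kind on those outputs, and applies it to the base models' test outputs.
#'
#' @param strategy one of `"rad"`, `"top"`, `"concat"`, `"vote"`, `"stack"`.
#' @param kind model family, see [train_predict()].
#' @param train,test data frames holding the feature blocks and the outcome.
#' @param outcome_col name of the outcome column.
#' @param blocks named character vector of block column prefixes.
#' @param k number of mRMR-selected features per block path.
#' @param task `"classification"` or `"regression"` (`NULL` = infer).
#' @param seed integer seed.
#' @return numeric vector of test scores.
#' @export
combine_blocks <- function(strategy, kind, train, test, outcome_col,
                           blocks = c(rad = "rad_", top = "top_"), k = 10,
                           task = NULL, seed = 1) {
  strategy <- match.arg(strategy, c("rad", "top", "concat", "vote", "stack"))
  y_tr <- train[[outcome_col]]
  if (is.null(task))
    task <- if (is.numeric(y_tr)) "regression" else "classification"
  if (task == "classification") y_tr <- factor(y_tr)
  cols_rad <- block_columns(train, blocks[["rad"]])
  cols_top <- block_columns(train, blocks[["top"]])
  run <- function(cols) block_scores(cols, kind, train, test, y_tr, task, k,
                                     seed)
  switch(strategy,
    rad = run(cols_rad),
    top = run(cols_top),
    concat = run(c(cols_rad, cols_top)),
    vote = (run(cols_rad) + run(cols_top)) / 2,
    stack = stack_scores(kind, train, test, y_tr, cols_rad, cols_top, task,
                         k, seed))
}

stack_scores <- function(kind, train, test, y_tr, cols_rad, cols_top, task,
                         k, seed, inner_folds = 5L) {
  n <- nrow(train)
  if (task == "classification" && min(table(y_tr)) < inner_folds)
    rlang::abort(paste0("too few training examples of a class for the ",
                        "internal ", inner_folds, "-fold stacking split"),
                 class = "topohist_stack_skip")
  fold <- with_seed(seed + 7L, {
    f <- integer(n)
    if (task == "classification") {
      for (lv in levels(y_tr)) {
        idx <- sample(which(y_tr == lv))
        f[idx] <- rep_len(seq_len(inner_folds), length(idx))
      }
    } else {
      f[sample(n)] <- rep_len(seq_len(inner_folds), n)
    }
    f
  })
  oof <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("rad_out", "top_out")))
  for (fd in seq_len(inner_folds)) {
    tr_i <- fold != fd
    oof[!tr_i, 1] <- block_scores(cols_rad, kind, train[tr_i, , drop = FALSE],
                                  train[!tr_i, , drop = FALSE], y_tr[tr_i],
                                  task, k, seed)
    oof[!tr_i, 2] <- block_scores(cols_top, kind, train[tr_i, , drop = FALSE],
                                  train[!tr_i, , drop = FALSE], y_tr[tr_i],
                                  task, k, seed)
  }
  base_te <- cbind(
    rad_out = block_scores(cols_rad, kind, train, test, y_tr, task, k, seed),
    top_out = block_scores(cols_top, kind, train, test, y_tr, task, k, seed))
  train_predict(kind, as.data.frame(oof), y_tr, as.data.frame(base_te),
                task = task, seed = seed)
}
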