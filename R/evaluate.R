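#' Cross-validation fold assignments
#'
#' Builds `repeats` seeded partitions of the nodules into `folds` folds,
#' reused across every strategy and model of an experiment. Sampling
#' schemes: `stratified_nodule` balances class counts across folds (within
#' one); `grouped_patient_random` assigns whole patients to folds so nodules
#' of one patient never split across folds; `grouped_patient_stratified`
#' additionally stratifies patients on a patient-level class (a patient is
#' labeled with the positive class if any of its nodules is positive).
#'
#' @param table tibble with `nodule_id`, `patient_id` and, for stratified
#'   schemes, `class_label`.
#' @param folds number of folds (default 5).
#' @param repeats number of repeated partitions (default 10).
#' @param sampling one of `"stratified_nodule"`, `"grouped_patient_random"`,
#'   `"grouped_patient_stratified"`.
#' @param seed integer seed; assignments are a pure function of the inputs.
#' @return tibble with columns `repeat_id`, `nodule_id`, `fold`.
#' @export
make_folds <- function(table, folds = 5, repeats = 10,
                       sampling = c("stratified_nodule",
                                    "grouped_patient_random",
                                    "grouped_patient_stratified"),
                       seed = 1) {
  sampling <- match.arg(sampling)
  stopifnot(folds >= 2, repeats >= 1)
  if (anyDuplicated(table$nodule_id)) stop("duplicate nodule_id")
  if (sampling != "grouped_patient_random") {
    cls <- table(table$class_label)
    if (length(cls) < 2) stop("stratified sampling needs both classes present")
    if (min(cls) < folds)
      stop(sprintf("class '%s' has %d members, fewer than %d folds",
                   names(cls)[which.min(cls)], min(cls), folds))
  }
  if (startsWith(sampling, "grouped") &&
      length(unique(table$patient_id)) < folds)
    stop("fewer patients than folds")
  with_seed(seed, {
    purrr::map(seq_len(repeats), function(r) {
      fold <- integer(nrow(table))
      if (sampling == "stratified_nodule") {
        for (lv in unique(table$class_label)) {
          idx <- sample(which(table$class_label == lv))
          fold[idx] <- rep_len(sample(folds), length(idx))
        }
      } else {
        pats <- unique(table$patient_id)
        if (sampling == "grouped_patient_random") {
          counts <- integer(folds)
          for (p in sample(pats)) {
            rows <- which(table$patient_id == p)
            f <- which.min(counts)
            fold[rows] <- f
            counts[f] <- counts[f] + length(rows)
          }
        } else {
          pos <- levels(factor(table$class_label))[2]
          plab <- vapply(pats, function(p)
            any(table$class_label[table$patient_id == p] == pos), logical(1))
          for (lv in c(TRUE, FALSE)) {
            grp <- sample(pats[plab == lv])
            ff <- rep_len(sample(folds), length(grp))
            for (i in seq_along(grp))
              fold[table$patient_id == grp[i]] <- ff[i]
          }
        }
      }
      tibble::tibble(repeat_id = r, nodule_id = table$nodule_id, fold = fold)
    }) |> dplyr::bind_rows()
  })
}

#' ROC AUC (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive instance is scored above
#' a randomly chosen negative one, with ties counted one half. The positive
#' class is the second factor level of `labels` (or `TRUE`/`1`).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels two-class labels.
#' @return AUC in `[0, 1]`, or `NA` (with a message) if only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) {
    message("roc_auc undefined: only one class present")
    return(NA_real_)
  }
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; can be negative for predictions worse than the
#' mean, and is undefined (`NA`, with a message) for constant truth.
#'
#' @param pred,truth numeric vectors of equal length.
#' @return r-squared, at most 1.
#' @export
r_squared <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    message("r_squared undefined: constant truth")
    return(NA_real_)
  }
  1 - sum((truth - pred)^2) / ss_tot
}

#' Paired one-sided comparison of two CV strategies
#'
#' Tests the null hypothesis that the reference strategy's mean fold score
#' is at least as good as the alternative's, over matched fold scores
#' (identical fold assignments). Fold scores of a (repeated) cross-
#' validation are positively correlated through the shared data, so the
#' plain paired t-test is anti-conservative; the default therefore applies
#' the Nadeau-Bengio variance correction for resampled scores, which
#' inflates the variance of the mean difference by
#' `1/J + test_train_ratio` (J matched scores). The uncorrected paired
#' t-test and a Wilcoxon signed-rank test remain available. A constant
#' nonzero difference (degenerate for all three) is reported as a
#' machine-epsilon bound with attribute `degenerate = TRUE`.
#'
#' @param ref,alt numeric vectors of matched fold scores (e.g. rad and vote).
#' @param method `"t_corrected"` (default), `"t"`, or `"wilcoxon"`.
#' @param test_train_ratio test-to-train size ratio of one fold, used by the
#'   correction; `1/(folds - 1)` for K-fold CV (default 1/4 for 5 folds).
#' @return one-sided p-value for H0: mean(ref) >= mean(alt).
#' @export
compare_strategies <- function(ref, alt,
                               method = c("t_corrected", "t", "wilcoxon"),
                               test_train_ratio = 1 / 4) {
  method <- match.arg(method)
  if (length(ref) != length(alt)) stop("mismatched score vectors")
  ok <- complete.cases(ref, alt)
  d <- alt[ok] - ref[ok]
  if (length(d) < 2) stop("need at least 2 matched scores")
  if (sd(d) == 0) {
    p <- if (mean(d) > 0) .Machine$double.eps
         else if (mean(d) < 0) 1 - .Machine$double.eps else 0.5
    return(structure(p, degenerate = TRUE, method = method))
  }
  p <- switch(method,
    t_corrected = {
      j <- length(d)
      se <- sd(d) * sqrt(1 / j + test_train_ratio)
      stats::pt(mean(d) / se, df = j - 1, lower.tail = FALSE)
    },
    t = t.test(alt[ok], ref[ok], paired = TRUE,
               alternative = "greater")$p.value,
    wilcoxon = suppressWarnings(
      wilcox.test(alt[ok], ref[ok], paired = TRUE,
                  alternative = "greater", exact = FALSE))$p.value)
  structure(p, degenerate = FALSE, method = method)
}

#' Run the full benchmark experiment on a feature table
#'
#' For every strategy x model family, scores `repeats x folds`
#' cross-validated predictions of the outcome, with fold assignments shared
#' across all strategies and models. All preprocessing, feature selection
#' and (base) model fitting happen inside each training fold. Classification
#' problems are scored by ROC AUC, regression by r-squared; the mean
#' performance is the mean over all fold scores. For each model family the
#' one-sided paired p-value of "vote beats rad" is computed from the matched
#' fold scores. Undefined metrics and recorded skips (e.g. too few examples
#' of a class for the internal stacking split) appear in the result's `log`.
#'
#' @param features tibble from [extract_features()] (or same shape).
#' @param outcome_col outcome column: `"class_label"` (classification) or
#'   `"malignancy_score"` (regression).
#' @param strategies subset of `c("rad","top","concat","vote","stack")`.
#' @param kinds subset of `c("LR","RF","KNN","SV","BAY","XGB")`.
#' @param folds,repeats CV geometry (protocol default: 5-fold, 10 repeats).
#' @param sampling fold sampling scheme, see [make_folds()].
#' @param k mRMR selection size.
#' @param comparison_method `"t_corrected"`, `"t"` or `"wilcoxon"`, see
#'   [compare_strategies()].
#' @param seed integer seed; identical seeds give bit-identical reports.
#' @return a `cv_result` object: list with `scores` (per repeat/fold),
#'   `summary`, `comparisons`, `log` and `config`.
#' @export
run_experiment <- function(features, outcome_col = "class_label",
                           strategies = c("rad", "top", "concat", "vote",
                                          "stack"),
                           kinds = "LR", folds = 5, repeats = 10,
                           sampling = "stratified_nodule", k = 10,
                           comparison_method = "t_corrected", seed = 1) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  task <- if (is.numeric(features[[outcome_col]])) "regression"
          else "classification"
  fold_tbl <- make_folds(features, folds = folds, repeats = repeats,
                         sampling = sampling, seed = seed)
  log_rows <- list()
  # constant features (e.g. a diagram count that never varies) are routine in
  # the 290-entry topological block; their per-fold warnings are muffled here
  quiet_fold <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("constant training feature|no observed training values",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  note <- function(r, f, strat, kind, msg) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      repeat_id = r, fold = f, strategy = strat, model = kind, event = msg)
  }
  score_fun <- function(sc, truth) {
    if (task == "classification") roc_auc(sc, truth) else r_squared(sc, truth)
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    fr <- fold_tbl[fold_tbl$repeat_id == r, ]
    for (f in seq_len(folds)) {
      te_ids <- fr$nodule_id[fr$fold == f]
      te <- features[features$nodule_id %in% te_ids, , drop = FALSE]
      tr <- features[!features$nodule_id %in% te_ids, , drop = FALSE]
      truth <- te[[outcome_col]]
      for (kind in kinds) {
        base <- list()
        for (blk in c("rad", "top")) {
          if (any(c(blk, "vote") %in% strategies)) {
            base[[blk]] <- tryCatch(
              quiet_fold(combine_blocks(blk, kind, tr, te, outcome_col,
                                        k = k, task = task, seed = seed)),
              error = function(e) {
                note(r, f, blk, kind, conditionMessage(e)); NULL
              })
          }
        }
        for (strat in strategies) {
          sc <- switch(strat,
            rad = base$rad,
            top = base$top,
            vote = if (!is.null(base$rad) && !is.null(base$top))
              (base$rad + base$top) / 2,
            tryCatch(
              quiet_fold(combine_blocks(strat, kind, tr, te, outcome_col,
                                        k = k, task = task, seed = seed)),
              topohist_stack_skip = function(e) {
                note(r, f, strat, kind, conditionMessage(e)); NULL
              },
              error = function(e) {
                note(r, f, strat, kind, conditionMessage(e)); NULL
              }))
          val <- if (is.null(sc)) NA_real_ else {
            withCallingHandlers(score_fun(sc, truth), message = function(m) {
              note(r, f, strat, kind, conditionMessage(m))
              invokeRestart("muffleMessage")
            })
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            strategy = strat, model = kind, repeat_id = r, fold = f,
            score = val, n_test = nrow(te))
        }
      }
    }
  }
  scores <- dplyr::bind_rows(rows)
  summary <- scores |>
    dplyr::group_by(.data$strategy, .data$model) |>
    dplyr::summarise(mean_score = mean(.data$score, na.rm = TRUE),
                     sd_score = sd(.data$score, na.rm = TRUE),
                     n_scores = sum(!is.na(.data$score)), .groups = "drop")
  comparisons <- NULL
  if (all(c("rad", "vote") %in% strategies)) {
    comparisons <- purrr::map(kinds, function(kind) {
      wide <- scores |>
        dplyr::filter(.data$model == kind,
                      .data$strategy %in% c("rad", "vote")) |>
        tidyr::pivot_wider(id_cols = c("repeat_id", "fold"),
                           names_from = "strategy", values_from = "score")
      p <- compare_strategies(wide$rad, wide$vote,
                              method = comparison_method,
                              test_train_ratio = 1 / (folds - 1))
      tibble::tibble(model = kind, p_vote_ge_rad = as.numeric(p),
                     degenerate = attr(p, "degenerate"))
    }) |> dplyr::bind_rows()
  }
  structure(list(scores = scores, summary = summary,
                 comparisons = comparisons,
                 log = if (length(log_rows)) dplyr::bind_rows(log_rows)
                       else tibble::tibble(),
                 config = list(outcome_col = outcome_col, task = task,
                               strategies = strategies, kinds = kinds,
                               folds = folds, repeats = repeats,
                               sampling = sampling, k = k, seed = seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s of '%s': %d repeats x %d folds, %s sampling\n",
              x$config$task, x$config$outcome_col, x$config$repeats,
              x$config$folds, x$config$sampling))
  wide <- x$summary |>
    dplyr::mutate(mean_score = round(100 * .data$mean_score, 1)) |>
    tidyr::pivot_wider(id_cols = "model", names_from = "strategy",
                       values_from = "mean_score")
  print(as.data.frame(wide), row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("p (vote >= rad):",
        paste(sprintf("%s %.2g", x$comparisons$model,
                      x$comparisons$p_vote_ge_rad), collapse = ", "), "\n")
  }
  if (nrow(x$log)) cat(nrow(x$log), "logged event(s); see $log\n")
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$scores

#' @export
glance.cv_result <- function(x, ...) {
  best <- x$summary[which.max(x$summary$mean_score), ]
  p <- if (!is.null(x$comparisons)) {
    row <- x$comparisons[x$comparisons$model == best$model, ]
    if (nrow(row)) row$p_vote_ge_rad else NA_real_
  } else NA_real_
  tibble::tibble(task = x$config$task, best_model = best$model,
                 best_strategy = best$strategy,
                 best_mean_score = best$mean_score,
                 p_vote_ge_rad = p,
                 n_scores = sum(!is.na(x$scores$score)),
                 n_logged = nrow(x$log))
}
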