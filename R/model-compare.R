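# Monte-Carlo subject-wise cross-validated model comparison: 9 models x 4
# feature-processing cells evaluated on identical train/test splits within
# each iteration, Wilcoxon-based model selection with the parsimony rule,
# and impurity-based random-forest feature importance.

#' Monte-Carlo subject-wise cross-validation of the model grid
#'
#' Per iteration, participants are split 90/10 (stratified by group, so
#' the test fold always contains both classes) and every
#' (model x selection x reduction) cell is trained and evaluated on the
#' identical split. Feature selection (top-`n_select` by univariate F) and
#' PCA reduction (`n_components` components) are fitted on training rows
#' only; missing values are imputed by the training median.
#'
#' @param matrix a `participant_matrix` from [build_matrix()]
#' @param iters number of Monte-Carlo iterations
#' @param seed integer seed controlling the split sequence
#' @param models subset of the nine model codes to run
#' @param cells feature-processing cells: tibble with logical `selection`,
#'   `reduction` columns (default: all four)
#' @param n_select,n_components selection/reduction sizes
#' @param test_frac test-fold fraction of participants
#' @return a `model_comparison`: tibble of per-iteration metrics with the
#'   run configuration in attributes
#' @export
monte_carlo_cv <- function(matrix, iters = 100, seed = 1,
                           models = MODEL_NAMES, cells = NULL,
                           n_select = 100, n_components = 10,
                           test_frac = 0.1) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  if (is.null(cells)) {
    cells <- tidyr::expand_grid(selection = c(TRUE, FALSE),
                                reduction = c(TRUE, FALSE))
  }
  feat_cols <- setdiff(names(matrix), c("participant_id", "group"))
  groups <- matrix$group
  if (min(table(groups)) < 2) stop("need at least 2 participants per group")
  selection_vacuous <- length(feat_cols) <= n_select
  if (selection_vacuous && any(cells$selection)) {
    warning("only ", length(feat_cols), " features available; ",
            "selection cells retain all of them")
  }
  rows <- list()
  for (it in seq_len(iters)) {
    split <- with_seed_(child_seed(seed, "split", it),
                        stratified_split(groups, test_frac))
    tr <- matrix[split$train, ]; te <- matrix[split$test, ]
    y_tr <- tr$group; y_te <- te$group
    for (ci in seq_len(nrow(cells))) {
      sel <- cells$selection[ci]; red <- cells$reduction[ci]
      keep <- if (sel && !selection_vacuous) {
        select_features(tr, n = n_select)
      } else feat_cols
      imp <- impute_train_median(tr[, keep, drop = FALSE],
                                 te[, keep, drop = FALSE])
      x_tr <- imp$train; x_te <- imp$test
      if (red) {
        proj <- reduce_features(x_tr, n_components = n_components)
        x_tr <- predict(proj, x_tr)
        x_te <- predict(proj, x_te)
      }
      for (m in models) {
        fit <- fit_model(m, x_tr, y_tr, seed = child_seed(seed, "fit", it, m, ci))
        sc <- predict_scores(fit, x_te)
        met <- classification_metrics(y_te, sc)
        rows[[length(rows) + 1]] <- tibble::tibble(
          iteration = it, model = m, selection = sel, reduction = red,
          accuracy = met["accuracy"], sensitivity = met["sensitivity"],
          specificity = met["specificity"], auc = met["auc"])
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, models = models, iters = iters, seed = seed,
            class = c("model_comparison", class(out)))
}

# Stratified subject-wise split: ceil(test_frac * n) per cohort overall,
# with at least one test participant per group.
stratified_split <- function(groups, test_frac = 0.1) {
  test <- integer(0)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    n_test <- max(1, round(test_frac * length(idx)))
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(groups), test), test = sort(test))
}

#' Summarize a model-comparison run per grid cell
#'
#' @param result a `model_comparison`
#' @return tibble of per-cell median and IQR of each metric
#' @export
summarize_cells <- function(result) {
  result |>
    dplyr::group_by(.data$model, .data$selection, .data$reduction) |>
    dplyr::summarise(dplyr::across(c("accuracy", "sensitivity",
                                     "specificity", "auc"),
                                   list(median = ~ median(.x, na.rm = TRUE),
                                        iqr = ~ iqr_(.x))),
                     .groups = "drop")
}

#' Select the best model under the parsimony rule
#'
#' The top cell by median accuracy anchors a candidate set of cells whose
#' paired accuracy samples are statistically indistinguishable from it
#' (two-sided Wilcoxon signed-rank, alpha = 0.05, no correction). Within
#' the candidates, the cell with the fewest feature-processing steps wins;
#' remaining ties break by a documented model-complexity order.
#'
#' @param result a `model_comparison`
#' @param alpha Wilcoxon significance level
#' @return one-row tibble: `model`, `selection`, `reduction`,
#'   `median_accuracy`, `n_candidates`
#' @export
select_model <- function(result, alpha = 0.05) {
  wide <- result |>
    dplyr::mutate(cell = paste(.data$model, .data$selection,
                               .data$reduction, sep = "|"))
  meds <- wide |>
    dplyr::group_by(.data$cell, .data$model, .data$selection, .data$reduction) |>
    dplyr::summarise(median_accuracy = median(.data$accuracy, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$median_accuracy))
  top <- meds$cell[1]
  acc_top <- wide$accuracy[wide$cell == top]
  indist <- vapply(meds$cell, function(cl) {
    if (cl == top) return(TRUE)
    a <- wide$accuracy[wide$cell == cl]
    ok <- is.finite(a) & is.finite(acc_top)
    if (sum(ok) < 3 || all(a[ok] == acc_top[ok])) return(TRUE)
    suppressWarnings(wilcox.test(a[ok], acc_top[ok], paired = TRUE,
                                 exact = FALSE)$p.value) > alpha
  }, logical(1))
  cand <- meds[indist, ]
  cand$steps <- cand$selection + cand$reduction
  cand$complexity <- MODEL_COMPLEXITY[cand$model]
  cand <- dplyr::arrange(cand, .data$steps, .data$complexity)
  dplyr::mutate(cand[1, c("model", "selection", "reduction", "median_accuracy")],
                n_candidates = nrow(cand))
}

#' Impurity-based feature importance from a random forest
#'
#' Fits a probability forest on the full matrix and returns mean-decrease-
#' in-impurity importances normalized to sum to one, ranked.
#'
#' @param matrix a `participant_matrix`
#' @param seed integer seed
#' @param num_trees forest size
#' @return tibble: `rank`, `feature`, `assessment`, `importance`
#' @export
rf_feature_importance <- function(matrix, seed = 1, num_trees = 100) {
  feat_cols <- setdiff(names(matrix), c("participant_id", "group"))
  imp <- impute_train_median(matrix[, feat_cols, drop = FALSE])
  x <- imp$train
  colnames(x) <- feat_cols
  fit <- ranger::ranger(x = x, y = factor(matrix$group, c("HC", "PD")),
                        probability = TRUE, num.trees = num_trees,
                        importance = "impurity", num.threads = 1,
                        seed = check_seed(seed))
  v <- fit$variable.importance
  v <- pmax(v, 0)
  v <- v / sum(v)
  tibble::tibble(feature = names(v), assessment = feature_assessment(names(v)),
                 importance = as.numeric(v)) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Cumulative importance distribution by feature group
#'
#' For features ordered by decreasing importance, the cumulative
#' proportion of each group's features encountered, with the chance
#' diagonal as reference.
#'
#' @param ranking tibble from [rf_feature_importance()]
#' @param grouping `"assessment"` or `"device"` (device parsed from
#'   gait/balance feature names; other features are tagged `other`)
#' @return an `importance_cdf` tibble: `rank`, `frac_ranked`, `group`,
#'   `cum_prop`
#' @export
importance_cdf <- function(ranking, grouping = c("assessment", "device")) {
  grouping <- match.arg(grouping)
  grp <- if (grouping == "assessment") {
    ranking$assessment
  } else {
    dplyr::case_when(
      grepl("\\.watch\\.", ranking$feature) ~ "watch",
      grepl("\\.phone\\.", ranking$feature) ~ "phone",
      grepl("\\.coh\\.", ranking$feature) ~ "synchronization",
      TRUE ~ "other")
  }
  n <- nrow(ranking)
  out <- lapply(unique(grp), function(g) {
    tibble::tibble(rank = seq_len(n), frac_ranked = seq_len(n) / n,
                   group = g, cum_prop = cumsum(grp == g) / sum(grp == g))
  })
  structure(dplyr::bind_rows(out), class = c("importance_cdf",
                                             class(ranking)))
}

#' Record-wise vs subject-wise cross-validation demonstration
#'
#' Runs the identical split-train-test pipeline on session-level feature
#' rows, splitting once by session (record-wise) and once by participant
#' (subject-wise). With subject random effects and no group effect,
#' record-wise splitting leaks subject identity into the test fold and
#' inflates accuracy; the returned `inflation` is the mean record-wise
#' minus mean subject-wise accuracy.
#'
#' @param session_features tibble from [extract_cohort()]
#' @param iters Monte-Carlo iterations
#' @param seed integer seed
#' @param model model code used for both arms
#' @param test_frac test fraction
#' @return list with per-iteration `accuracy` tibble and scalar
#'   `inflation`
#' @export
recordwise_vs_subjectwise_demo <- function(session_features, iters = 20,
                                           seed = 1, model = "RF",
                                           test_frac = 0.1) {
  feat_cols <- setdiff(names(session_features), session_key_cols())
  x_all <- as.matrix(session_features[, feat_cols])
  y_all <- session_features$group
  pid <- session_features$participant_id
  run_split <- function(train_idx, test_idx, it) {
    imp <- impute_train_median(x_all[train_idx, , drop = FALSE],
                               x_all[test_idx, , drop = FALSE])
    fit <- fit_model(model, imp$train, y_all[train_idx],
                     seed = child_seed(seed, "fit", it))
    met <- classification_metrics(y_all[test_idx],
                                  predict_scores(fit, imp$test))
    met["accuracy"]
  }
  rows <- list()
  for (it in seq_len(iters)) {
    rec <- with_seed_(child_seed(seed, "rec", it), {
      n <- length(y_all)
      test <- sample.int(n, max(2, round(test_frac * n)))
      list(train = setdiff(seq_len(n), test), test = test)
    })
    sub <- with_seed_(child_seed(seed, "sub", it), {
      ids <- unique(pid)
      gid <- y_all[match(ids, pid)]
      ts <- stratified_split(gid, test_frac)
      list(train = which(pid %in% ids[ts$train]),
           test = which(pid %in% ids[ts$test]))
    })
    rows[[it]] <- tibble::tibble(
      iteration = it,
      recordwise = run_split(rec$train, rec$test, it),
      subjectwise = run_split(sub$train, sub$test, it + 10000L))
  }
  acc <- dplyr::bind_rows(rows)
  list(accuracy = acc,
       inflation = mean(acc$recordwise, na.rm = TRUE) -
         mean(acc$subjectwise, na.rm = TRUE))
}
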