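test_that("classification metrics follow the 2x2 table arithmetic", {
  # TP 9, FN 1, TN 4, FP 0
  labels <- c(rep("PD", 10), rep("HC", 4))
  scores <- c(rep(0.9, 9), 0.1, rep(0.2, 4))
  met <- classification_metrics(labels, scores)
  expect_equal(unname(met["sensitivity"]), 0.9)
  expect_equal(unname(met["specificity"]), 1.0)
  expect_equal(unname(met["accuracy"]), 13 / 14)

  expect_equal(unname(classification_metrics(labels, rep(0.5, 14))["auc"]), 0.5)
  one_class <- classification_metrics(rep("PD", 5), rep(0.9, 5))
  expect_true(is.na(one_class["specificity"]))
  expect_true(is.na(one_class["auc"]))
})

test_that("rank-statistic AUC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (rep in 1:5) {
    labels <- sample(c("PD", "HC"), 40, replace = TRUE, prob = c(0.6, 0.4))
    scores <- runif(40) + 0.3 * (labels == "PD")
    ours <- unname(classification_metrics(labels, scores)["auc"])
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(labels, scores, levels = c("HC", "PD"),
                          direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("every model learns a linearly separable problem", {
  set.seed(7)
  n <- 60
  g <- rep(c("PD", "HC"), each = n / 2)
  x <- matrix(rnorm(n * 5), n)
  x[g == "PD", 1] <- x[g == "PD", 1] + 6
  for (m in c("LR", "LDA", "SVM", "DT", "GBT", "RF", "SGD", "GNB", "MP")) {
    fit <- fit_model(m, x[1:50, ], g[1:50], seed = 1)
    sc <- predict_scores(fit, x[51:60, , drop = FALSE])
    met <- classification_metrics(g[51:60], sc)
    expect_gte(unname(met["accuracy"]), 0.9)
  }
})

test_that("Monte-Carlo CV: shared splits, determinism, fold sizes, separable limit", {
  set.seed(8)
  n <- 30
  g <- rep(c("PD", "HC"), c(18, 12))
  x <- matrix(rnorm(n * 6), n)
  # the group contrast spans several features so it survives every
  # processing cell (including PCA on z-scored columns) intact
  x[g == "PD", 1:4] <- x[g == "PD", 1:4] + 6
  m <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%02d", 1:n), group = g),
    tibble::as_tibble(setNames(as.data.frame(x), paste0("f", 1:6))))
  expect_warning(mc <- monte_carlo_cv(m, iters = 4, seed = 9,
                                      models = c("LR", "RF")),
                 "retain all")
  expect_equal(nrow(mc), 4 * 4 * 2) # iters x cells x models
  expect_true(all(mc$accuracy == 1))
  mc2 <- suppressWarnings(monte_carlo_cv(m, iters = 4, seed = 9,
                                         models = c("LR", "RF")))
  expect_identical(tibble::as_tibble(mc), tibble::as_tibble(mc2))

  # a 132-participant cohort yields stratified test folds of 13-14
  groups132 <- rep(c("PD", "HC"), c(82, 50))
  set.seed(1)
  sp <- digibm:::stratified_split(groups132, 0.1)
  expect_true(length(sp$test) %in% 13:14)
  expect_true(all(table(groups132[sp$test]) >= 1))
})

test_that("model selection applies the Wilcoxon-parsimony rule", {
  cellgrid <- tidyr::expand_grid(
    model = c("LR", "RF"), selection = c(TRUE, FALSE), reduction = c(TRUE, FALSE))
  mk <- function(acc_fun) {
    dplyr::bind_rows(lapply(seq_len(nrow(cellgrid)), function(i) {
      tibble::tibble(iteration = 1:30, model = cellgrid$model[i],
                     selection = cellgrid$selection[i],
                     reduction = cellgrid$reduction[i],
                     accuracy = acc_fun(cellgrid[i, ]),
                     sensitivity = 0.5, specificity = 0.5, auc = 0.5)
    }))
  }
  # one cell strictly dominates
  set.seed(10)
  dom <- mk(function(cell) {
    if (cell$model == "RF" && !cell$selection && !cell$reduction) {
      0.95 + rnorm(30, sd = 0.01)
    } else 0.6 + rnorm(30, sd = 0.01)
  })
  pick <- select_model(dom)
  expect_equal(pick$model, "RF")
  expect_false(pick$selection || pick$reduction)

  # statistical tie: minimal-processing, least-complex cell wins
  tie <- mk(function(cell) rep(c(0.8, 0.81), 15))
  pick2 <- select_model(tie)
  expect_equal(pick2$model, "LR")
  expect_false(pick2$selection || pick2$reduction)
  expect_equal(pick2$n_candidates, 8)
})

test_that("random-forest importance finds a planted feature and normalizes", {
  set.seed(11)
  n <- 60
  g <- rep(c("PD", "HC"), each = n / 2)
  x <- matrix(rnorm(n * 30), n)
  x[, 7] <- x[, 7] + 3 * (g == "PD")
  m <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%02d", 1:n), group = g),
    tibble::as_tibble(setNames(as.data.frame(x), sprintf("tremor.f%02d", 1:30))))
  imp <- rf_feature_importance(m, seed = 2)
  expect_equal(imp$feature[1], "tremor.f07")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)

  cdf <- importance_cdf(imp)
  expect_equal(max(cdf$cum_prop), 1)
  expect_equal(nrow(cdf), 30)
})

test_that("record-wise splitting inflates accuracy under subject random effects", {
  set.seed(12)
  n_subj <- 24
  subj_eff <- matrix(rnorm(n_subj * 10, sd = 2), n_subj)
  rows <- do.call(rbind, lapply(1:n_subj, function(i) {
    t(replicate(4, subj_eff[i, ] + rnorm(10, sd = 0.3)))
  }))
  sf <- dplyr::bind_cols(
    tibble::tibble(participant_id = rep(sprintf("P%02d", 1:n_subj), each = 4),
                   group = rep(rep(c("PD", "HC"), each = n_subj / 2), each = 4),
                   environment = "home",
                   visit_index = rep(0:3, n_subj),
                   visit_time = rep(c(0, 14, 28, 42), n_subj)),
    tibble::as_tibble(setNames(as.data.frame(rows), paste0("f", 1:10))))
  demo <- recordwise_vs_subjectwise_demo(sf, iters = 8, seed = 13)
  expect_gt(demo$inflation, 0.1)
  expect_lt(abs(mean(demo$accuracy$subjectwise) - 0.5), 0.35)
})
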