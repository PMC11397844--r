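# Cross-environment generalization: a 2 (training environment) x 2 (test
# environment) x 2 (same vs independent cohort) Monte-Carlo design on
# participants with both clinic and home feature vectors, followed by a
# repeated-measures ANOVA with iterations as the repeated unit.

#' Run the cross-environment generalization experiment
#'
#' Session features are averaged into one clinic vector and one home
#' vector per participant; only participants with both are analysed. Per
#' iteration the participants are split into training and held-out
#' cohorts; the model is trained on the training cohort's features from
#' each training environment and evaluated on every (test environment x
#' cohort) combination. Same-cohort predictions on the identical
#' (environment, cohort) data the model was trained on are computed but
#' flagged `overfit_flag = TRUE` so they can be quarantined from
#' inference.
#'
#' @param session_features tibble from [extract_cohort()]
#' @param model model code (e.g. the [select_model()] winner)
#' @param iters Monte-Carlo iterations
#' @param seed integer seed
#' @param test_frac held-out cohort fraction
#' @return a `cross_env_result` tibble: iteration, train_env, test_env,
#'   cohort, metrics, overfit_flag
#' @export
run_cross_env <- function(session_features, model = "RF", iters = 100,
                          seed = 1, test_frac = 0.1) {
  clinic <- build_matrix(session_features, scope = "clinic")
  home <- build_matrix(session_features, scope = "home")
  common <- intersect(clinic$participant_id, home$participant_id)
  if (length(common) < 4) stop("need at least 4 participants with both environments")
  clinic <- clinic[match(common, clinic$participant_id), ]
  home <- home[match(common, home$participant_id), ]
  groups <- clinic$group
  feat_cols <- setdiff(names(clinic), c("participant_id", "group"))
  mats <- list(clinic = as.matrix(clinic[, feat_cols]),
               home = as.matrix(home[, feat_cols]))
  rows <- list()
  for (it in seq_len(iters)) {
    split <- with_seed_(child_seed(seed, "xsplit", it),
                        stratified_split(groups, test_frac))
    for (train_env in c("clinic", "home")) {
      imp <- impute_train_median(mats[[train_env]][split$train, , drop = FALSE])
      fit <- fit_model(model, imp$train, groups[split$train],
                       seed = child_seed(seed, "xfit", it, train_env))
      for (test_env in c("clinic", "home")) {
        for (cohort in c("same", "independent")) {
          idx <- if (cohort == "same") split$train else split$test
          xte <- mats[[test_env]][idx, , drop = FALSE]
          for (j in seq_len(ncol(xte))) {
            bad <- !is.finite(xte[, j])
            if (any(bad)) xte[bad, j] <- imp$medians[j]
          }
          met <- classification_metrics(groups[idx], predict_scores(fit, xte))
          rows[[length(rows) + 1]] <- tibble::tibble(
            iteration = it, train_env = train_env, test_env = test_env,
            cohort = cohort,
            accuracy = met["accuracy"], sensitivity = met["sensitivity"],
            specificity = met["specificity"], auc = met["auc"],
            overfit_flag = cohort == "same" && train_env == test_env)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, model = model, n_participants = length(common),
            class = c("cross_env_result", class(out)))
}

#' Repeated-measures ANOVA on cross-environment accuracy
#'
#' Three within factors (training environment, test environment, cohort)
#' with Monte-Carlo iterations as the repeated unit; reports main effects
#' and all interactions.
#'
#' @param result a `cross_env_result`
#' @param metric metric column to analyse
#' @return tibble: effect, df1, df2, statistic (F), p_value
#' @export
rm_anova <- function(result, metric = "accuracy") {
  df <- tibble::tibble(
    y = result[[metric]],
    iter = factor(result$iteration),
    train_env = factor(result$train_env),
    test_env = factor(result$test_env),
    cohort = factor(result$cohort))
  df <- df[is.finite(df$y), ]
  if (stats::var(df$y) < 1e-24) {
    # degenerate inputs: identical accuracy in every cell
    effects <- c("train_env", "test_env", "cohort",
                 "train_env:test_env", "train_env:cohort",
                 "test_env:cohort", "train_env:test_env:cohort")
    return(tibble::tibble(effect = effects, df1 = 1,
                          df2 = nlevels(df$iter) - 1,
                          statistic = 0, p_value = 1))
  }
  fit <- aov(y ~ train_env * test_env * cohort +
               Error(iter / (train_env * test_env * cohort)), data = df)
  out <- list()
  for (stratum in names(summary(fit))) {
    tab <- summary(fit)[[stratum]][[1]]
    terms <- trimws(rownames(tab))
    keep <- terms != "Residuals"
    if (!any(keep)) next
    res_df <- tab[terms == "Residuals", "Df"]
    for (k in which(keep)) {
      out[[length(out) + 1]] <- tibble::tibble(
        effect = terms[k], df1 = tab[k, "Df"], df2 = res_df,
        statistic = tab[k, "F value"], p_value = tab[k, "Pr(>F)"])
    }
  }
  dplyr::bind_rows(out)
}
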