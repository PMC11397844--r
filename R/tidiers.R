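# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_col geom_line
#'   geom_histogram geom_hline geom_abline facet_wrap labs theme_minimal
#'   position_dodge
#' @export
ggplot2::autoplot

#' Tidy a model-comparison result
#'
#' @param x a `model_comparison` from [monte_carlo_cv()]
#' @param ... unused
#' @return per-iteration metric tibble in long form
#' @export
tidy.model_comparison <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity", "auc"),
                        names_to = "metric", values_to = "value")
}

#' @param x a `model_comparison`
#' @param ... unused
#' @rdname tidy.model_comparison
#' @return one row per grid cell with median/IQR metrics; the selected
#'   cell is flagged
#' @export
glance.model_comparison <- function(x, ...) {
  cells <- summarize_cells(x)
  sel <- select_model(x)
  dplyr::mutate(cells, selected = .data$model == sel$model &
                  .data$selection == sel$selection &
                  .data$reduction == sel$reduction)
}

#' @param object a `model_comparison`
#' @param metric metric to display
#' @param ... unused
#' @rdname tidy.model_comparison
#' @export
autoplot.model_comparison <- function(object, metric = "accuracy", ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(processing = paste0("sel", ifelse(.data$selection, "+", "-"),
                                      " red", ifelse(.data$reduction, "+", "-")))
  ggplot(df, aes(x = .data$model, y = .data[[metric]],
                 fill = .data$processing)) +
    geom_boxplot(outlier.size = 0.4, position = position_dodge(width = 0.8)) +
    labs(x = NULL, y = metric, fill = "processing") +
    theme_minimal()
}

#' Tidy a cross-environment result
#'
#' @param x a `cross_env_result` from [run_cross_env()]
#' @param ... unused
#' @return the per-iteration condition table as a plain tibble
#' @export
tidy.cross_env_result <- function(x, ...) tibble::as_tibble(x)

#' @param x a `cross_env_result`
#' @param ... unused
#' @rdname tidy.cross_env_result
#' @return per-condition mean metrics (same-data train/test conditions
#'   flagged by `overfit_flag`)
#' @export
glance.cross_env_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$train_env, .data$test_env, .data$cohort,
                    .data$overfit_flag) |>
    dplyr::summarise(dplyr::across(c("accuracy", "sensitivity",
                                     "specificity", "auc"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' @param object a `cross_env_result`
#' @param ... unused
#' @rdname tidy.cross_env_result
#' @export
autoplot.cross_env_result <- function(object, ...) {
  df <- glance.cross_env_result(object)
  ggplot(df, aes(x = paste(.data$train_env, "->", .data$test_env),
                 y = .data$accuracy, fill = .data$cohort)) +
    geom_col(position = position_dodge()) +
    labs(x = "train -> test environment", y = "mean accuracy",
         fill = "cohort") +
    theme_minimal()
}

#' Plot a feature-selectivity distribution
#'
#' Histogram of the per-feature F statistics with the significance
#' threshold marked.
#'
#' @param object a `selectivity_table` from [selectivity_analysis()]
#' @param bins histogram bins
#' @param ... unused
#' @export
autoplot.selectivity_table <- function(object, bins = 60, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df[is.finite(df$statistic), ], aes(x = .data$statistic)) +
    geom_histogram(bins = bins) +
    labs(x = "F statistic", y = "features") +
    theme_minimal()
}

#' Plot cumulative feature-importance distributions
#'
#' @param object an `importance_cdf` from [importance_cdf()]
#' @param ... unused
#' @export
autoplot.importance_cdf <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$frac_ranked, y = .data$cum_prop,
             colour = .data$group)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "features ordered by importance (fraction)",
         y = "cumulative proportion of group") +
    theme_minimal()
}

#' Plot a reliability threshold summary
#'
#' @param object a `reliability_summary` from [threshold_summary()]
#' @param ... unused
#' @export
autoplot.reliability_summary <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$assessment, y = .data$prop_above)) +
    geom_col() +
    geom_hline(yintercept = 0.5, linetype = "dotted") +
    labs(x = NULL, y = paste0("proportion of features with ICC > ",
                              attr(object, "threshold"))) +
    theme_minimal()
}
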