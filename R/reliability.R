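# Feature-wise reliability: external (clinic vs home) and test-retest
# (across calendar-month bins) intraclass correlations, with the 0.6
# acceptance threshold summaries.

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' computed from the two-way ANOVA mean squares:
#' (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n).
#' Rows with any missing occasion are dropped (listwise deletion).
#'
#' @param m subjects x occasions numeric matrix
#' @return ICC coefficient in \[-1, 1\], or `NA` if fewer than 3 complete
#'   subjects remain
#' @export
icc <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) return(NA_real_)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_e <- sum((m - outer(row_m, rep(1, k)) -
                 outer(rep(1, n), col_m) + grand)^2)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  if (!is.finite(denom) || abs(denom) < 1e-300) {
    warning("zero between-subject variance; returning ICC 0")
    return(0)
  }
  (ms_r - ms_e) / denom
}

#' External (clinic vs home) reliability of every feature
#'
#' Occasion 1 is the participant's clinic mean, occasion 2 the home mean;
#' ICC(2,1) per feature across participants with both.
#'
#' @param session_features tibble from [extract_cohort()]
#' @return tibble: feature, assessment, icc, n_subjects
#' @export
external_reliability <- function(session_features) {
  clinic <- build_matrix(session_features, scope = "clinic")
  home <- build_matrix(session_features, scope = "home")
  common <- intersect(clinic$participant_id, home$participant_id)
  clinic <- clinic[match(common, clinic$participant_id), ]
  home <- home[match(common, home$participant_id), ]
  feat_cols <- setdiff(names(clinic), c("participant_id", "group"))
  vals <- vapply(feat_cols, function(f) {
    m <- cbind(clinic[[f]], home[[f]])
    suppressWarnings(icc(m))
  }, numeric(1))
  ns <- vapply(feat_cols, function(f) {
    sum(stats::complete.cases(cbind(clinic[[f]], home[[f]])))
  }, numeric(1))
  tibble::tibble(feature = feat_cols, assessment = feature_assessment(feat_cols),
                 icc = vals, n_subjects = ns)
}

#' Test-retest reliability of every feature across time bins
#'
#' Sessions are averaged within calendar-month bins of `bin_days` days;
#' ICC(2,1) per feature with bins as occasions. Participants present in
#' fewer than two bins are dropped (listwise per feature); the count of
#' dropped participants is attached as an attribute.
#'
#' @param session_features tibble from [extract_cohort()]
#' @param bin_days bin width in days
#' @return tibble: feature, assessment, icc, n_subjects
#' @export
retest_reliability <- function(session_features, bin_days = 30) {
  df <- dplyr::mutate(session_features,
                      bin = floor(.data$visit_time / bin_days))
  feat_cols <- setdiff(names(df), c(session_key_cols(), "bin"))
  binned <- df |>
    dplyr::group_by(.data$participant_id, .data$bin) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feat_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  bins <- sort(unique(binned$bin))
  single_bin <- binned |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n < 2)
  vals <- vapply(feat_cols, function(f) {
    wide <- tidyr::pivot_wider(binned[, c("participant_id", "bin", f)],
                               names_from = "bin", values_from = dplyr::all_of(f))
    m <- as.matrix(wide[, -1])
    suppressWarnings(icc(m))
  }, numeric(1))
  ns <- vapply(feat_cols, function(f) {
    wide <- tidyr::pivot_wider(binned[, c("participant_id", "bin", f)],
                               names_from = "bin", values_from = dplyr::all_of(f))
    sum(stats::complete.cases(as.matrix(wide[, -1])))
  }, numeric(1))
  structure(tibble::tibble(feature = feat_cols,
                           assessment = feature_assessment(feat_cols),
                           icc = vals, n_subjects = ns),
            n_bins = length(bins), n_dropped = nrow(single_bin))
}

#' Per-assessment reliability threshold summary
#'
#' For each assessment: the proportion of feature ICCs strictly above the
#' acceptance threshold, and a one-sided one-sample t-test of whether the
#' mean ICC exceeds the threshold. Optionally restricted to a subset of
#' features (e.g. the top-importance features).
#'
#' @param report tibble from [external_reliability()] or
#'   [retest_reliability()]
#' @param threshold ICC acceptance threshold
#' @param features optional character vector restricting the summary
#' @return a `reliability_summary` tibble: assessment, n, prop_above,
#'   mean_icc, statistic (t), p_value
#' @export
threshold_summary <- function(report, threshold = 0.6, features = NULL) {
  df <- report
  if (!is.null(features)) df <- df[df$feature %in% features, ]
  df <- df[is.finite(df$icc), ]
  out <- df |>
    dplyr::group_by(.data$assessment) |>
    dplyr::summarise(
      n = dplyr::n(),
      prop_above = mean(.data$icc > threshold),
      mean_icc = mean(.data$icc),
      statistic = unname(one_sample_t(.data$icc, threshold)["t"]),
      p_value = unname(one_sample_t(.data$icc, threshold)["p"]),
      .groups = "drop")
  structure(out, threshold = threshold,
            overall_prop_above = mean(df$icc > threshold),
            class = c("reliability_summary", class(out)))
}

one_sample_t <- function(x, mu) {
  n <- length(x)
  if (n < 2 || sd(x) < 1e-10 * max(1, abs(mean(x)))) {
    m <- mean(x)
    if (!is.finite(m)) return(c(t = NA_real_, p = NA_real_))
    if (m == mu) return(c(t = 0, p = 0.5))
    return(if (m > mu) c(t = Inf, p = 0) else c(t = -Inf, p = 1))
  }
  tt <- t.test(x, mu = mu, alternative = "greater")
  c(t = unname(tt$statistic), p = tt$p.value)
}
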