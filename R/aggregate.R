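# Feature wrangling: session rows merged on canonical names, averaged per
# participant into the modeling matrix; univariate selectivity analysis;
# and the parametric feature-selection / PCA-reduction routines (always
# fitted on training rows only).

#' Build the participant-level feature matrix
#'
#' Session feature rows are averaged per participant within the requested
#' environment scope, producing one row of features per participant.
#' Averaging skips missing values; features a participant never observed
#' stay missing.
#'
#' @param session_features tibble from [extract_cohort()]
#' @param scope `"all"`, `"clinic"` or `"home"`
#' @return a `participant_matrix` tibble: `participant_id`, `group`, then
#'   feature columns
#' @export
build_matrix <- function(session_features, scope = c("all", "clinic", "home")) {
  scope <- match.arg(scope)
  df <- session_features
  if (scope != "all") df <- dplyr::filter(df, .data$environment == scope)
  if (nrow(df) == 0) stop("no sessions in scope '", scope, "'")
  feat_cols <- setdiff(names(df), session_key_cols())
  out <- df |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feat_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(feat_cols),
                                          ~ ifelse(is.nan(.x), NA_real_, .x)))
  structure(out, scope = scope, class = c("participant_matrix", class(out)))
}

#' Feature-wise univariate selectivity analysis
#'
#' For every feature, a univariate linear regression of the feature on the
#' group label (equivalently a one-way F-test; F equals the square of the
#' pooled-variance two-sample t statistic). Per the exploratory design, no
#' multiple-comparison correction is applied.
#'
#' @param matrix a `participant_matrix` (or any tibble with a `group`
#'   column and numeric feature columns)
#' @param alpha significance threshold used for the reported proportions
#' @return a `selectivity_table` tibble: `feature`, `assessment`,
#'   `statistic` (F), `p_value`, `significant`; overall and per-assessment
#'   proportions in the `summary` attribute
#' @export
selectivity_analysis <- function(matrix, alpha = 0.05) {
  feat_cols <- setdiff(names(matrix), c("participant_id", "group"))
  g <- matrix$group == "PD"
  stat <- p <- rep(NA_real_, length(feat_cols))
  for (i in seq_along(feat_cols)) {
    y <- matrix[[feat_cols[i]]]
    ok <- is.finite(y)
    y1 <- y[ok & g]; y0 <- y[ok & !g]
    n1 <- length(y1); n0 <- length(y0)
    if (n1 < 2 || n0 < 2) next
    sp2 <- ((n1 - 1) * var(y1) + (n0 - 1) * var(y0)) / (n1 + n0 - 2)
    if (!is.finite(sp2) || sp2 <= 0) next
    tt <- (mean(y1) - mean(y0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
    stat[i] <- tt^2
    p[i] <- pf(stat[i], 1, n1 + n0 - 2, lower.tail = FALSE)
  }
  tab <- tibble::tibble(feature = feat_cols,
                        assessment = feature_assessment(feat_cols),
                        statistic = stat, p_value = p,
                        significant = !is.na(p) & p < alpha)
  summary <- tab |>
    dplyr::group_by(.data$assessment) |>
    dplyr::summarise(n = dplyr::n(),
                     prop_significant = mean(.data$significant),
                     .groups = "drop")
  structure(tab, summary = summary,
            prop_significant = mean(tab$significant),
            class = c("selectivity_table", class(tab)))
}

#' Select the most group-selective features
#'
#' Retains the `n` features with the highest univariate F statistic,
#' computed on training rows only. Ties break deterministically by
#' (F descending, name ascending). If fewer than `n` features are
#' available, all are retained with a warning.
#'
#' @param train a `participant_matrix` of training rows
#' @param n number of features to retain
#' @return character vector of retained feature names
#' @export
select_features <- function(train, n = 100) {
  tab <- selectivity_analysis(train)
  tab$statistic[is.na(tab$statistic)] <- -Inf
  ord <- order(-tab$statistic, tab$feature)
  if (nrow(tab) <= n) {
    if (nrow(tab) < n) {
      warning("only ", nrow(tab), " features available; retaining all")
    }
    return(tab$feature[ord])
  }
  tab$feature[ord][seq_len(n)]
}

#' Fit a principal-component reduction on training rows
#'
#' Features are z-scored with training statistics, then the `n_components`
#' components explaining the greatest variance are retained. Test rows are
#' transformed with the training parameters only.
#'
#' @param train numeric matrix / tibble of training feature columns
#' @param n_components number of components to keep
#' @return a `pca_reduction` with a [predict()] method
#' @export
reduce_features <- function(train, n_components = 10) {
  x <- as.matrix(train)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  k <- min(n_components, ncol(xs), nrow(xs) - 1)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  ev <- pc$sdev^2
  structure(list(mean = mu, sd = sdv, rotation = rot,
                 explained_variance = ev / sum(ev),
                 n_components = n_components),
            class = "pca_reduction")
}

#' @param object a `pca_reduction`
#' @param newdata matrix of rows to project
#' @param ... unused
#' @rdname reduce_features
#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$mean), 2, object$sd, "/")
  out <- xs %*% object$rotation
  colnames(out) <- paste0("PC", seq_len(ncol(out)))
  out
}

# Training-median imputation of missing feature values; medians are
# learned on the training rows and applied to both sets.
impute_train_median <- function(train, test = NULL) {
  med <- apply(train, 2, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.finite(m)) m else 0
  })
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      bad <- !is.finite(m[, j])
      if (any(bad)) m[bad, j] <- med[j]
    }
    m
  }
  list(train = fill(as.matrix(train)),
       test = if (is.null(test)) NULL else fill(as.matrix(test)),
       medians = med)
}
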