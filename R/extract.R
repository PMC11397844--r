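# Session-level feature extraction: every assessment's routine is run (or
# emitted as named missing values when the payload is absent) and the
# results are assembled into one row per session. A complete battery
# yields exactly 3621 named features.

#' Extract all features from one session
#'
#' Runs the full nine-assessment catalog on a `session_record`. Missing
#' payloads produce missing values under the full set of feature names,
#' never silently dropped columns.
#'
#' @param session a `session_record`
#' @param battery assessments to extract (defaults to the full registry;
#'   restricting the battery restricts the emitted names)
#' @return a one-row tibble: `participant_id`, `group`, `environment`,
#'   `visit_index`, `visit_time`, then one column per feature
#' @export
extract_session <- function(session, battery = assessment_registry()) {
  stopifnot(inherits(session, "session_record"))
  battery <- match.arg(battery, assessment_registry(), several.ok = TRUE)
  p <- session$payloads
  vals <- c()
  if ("vstm" %in% battery) vals <- c(vals, vstm_features(p$vstm))
  if ("sdmt" %in% battery) vals <- c(vals, sdmt_features(p$sdmt))
  if ("trails" %in% battery) {
    vals <- c(vals, trails_features(p$trails %||% list()))
  }
  if ("fine_motor" %in% battery) {
    vals <- c(vals, finemotor_features(p$fine_motor %||% list()))
  }
  if ("finger_tapping" %in% battery) {
    vals <- c(vals, tapping_features(p$finger_tapping %||% list()))
  }
  if ("phonation" %in% battery) {
    vals <- c(vals, extract_voice(p$phonation, "phonation"))
  }
  if ("articulation" %in% battery) {
    vals <- c(vals, extract_voice(p$articulation, "articulation"))
  }
  if ("tremor" %in% battery) {
    vals <- c(vals, extract_tremor(p$tremor %||% list()))
  }
  if ("gait_balance" %in% battery) {
    vals <- c(vals, extract_gaitbalance(p$gait_balance %||% list()))
  }
  dplyr::bind_cols(
    tibble::tibble(participant_id = session$participant_id,
                   group = session$group,
                   environment = session$environment,
                   visit_index = session$visit_index,
                   visit_time = session$visit_time),
    tibble::as_tibble(as.list(vals))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract features for every session of a cohort
#'
#' @param sessions list of `session_record`s (e.g. from
#'   [generate_cohort()])
#' @param battery assessments to extract
#' @param progress print a line every 25 sessions
#' @return tibble with one row per session (key columns + features)
#' @export
extract_cohort <- function(sessions, battery = assessment_registry(),
                           progress = FALSE) {
  rows <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    rows[[i]] <- extract_session(sessions[[i]], battery = battery)
    if (progress && i %% 25 == 0) {
      message(sprintf("extracted %d / %d sessions", i, length(sessions)))
    }
  }
  dplyr::bind_rows(rows)
}

#' The canonical feature catalog
#'
#' Enumerates every feature name the full extraction emits, with its
#' assessment tag, without touching any data.
#'
#' @param battery assessments to include
#' @return tibble with columns `feature` and `assessment`
#' @export
feature_catalog <- function(battery = assessment_registry()) {
  empty <- session_record("cat", "HC", "clinic", 0, 0, payloads = list())
  row <- extract_session(empty, battery = battery)
  nm <- setdiff(names(row), session_key_cols())
  tibble::tibble(feature = nm, assessment = feature_assessment(nm))
}

session_key_cols <- function() {
  c("participant_id", "group", "environment", "visit_index", "visit_time")
}

# Assessment tag = name prefix before the first ".".
feature_assessment <- function(feature) {
  sub("\\..*$", "", feature)
}
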