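# Synthetic cohort generation: a PD/HC study population with the
# statistical structure the downstream analyses assume — group differences
# entering through shifted parameter distributions, subject-level random
# effects shared across sessions, clinic and home environments, and a
# persisted ground-truth table for parameter-recovery tests.

ASSESSMENTS <- c("vstm", "sdmt", "trails", "fine_motor", "finger_tapping",
                 "phonation", "articulation", "tremor", "gait_balance")

#' Registry of the nine assessments
#' @return character vector of canonical assessment names
#' @export
assessment_registry <- function() ASSESSMENTS

# Baseline (HC) generator parameters and their fully-separated (PD) values.
# Effects are scaled by `effect_scale` in [0, 1]; at 0 the groups are
# exchangeable. Values are the package's one-time choice of a realistic
# early-stage contrast; see the methods vignette.
param_table <- function() {
  tibble::tribble(
    ~param,            ~hc,   ~pd,    ~dist,      ~sdlog_or_sd,
    "tremor_amp",      0.004, 0.040,  "lognormal", 0.4,
    "tremor_freq",     8.5,   5.5,    "uniform1.5", NA,
    "cadence",         1.90,  1.70,   "normal",    0.08,
    "arm_swing_amp",   0.150, 0.050,  "lognormal", 0.25,
    "timing_jitter",   0.020, 0.060,  "lognormal", 0.25,
    "jitter_pct",      0.50,  2.00,   "lognormal", 0.30,
    "shimmer_db",      0.30,  0.80,   "lognormal", 0.30,
    "hnr_db",          20.0,  12.0,   "normal",    1.5,
    "f0",              120,   118,    "normal",    12,
    "tap_mean_iti",    180,   250,    "lognormal", 0.12,
    "tap_sd_iti",      20,    60,     "lognormal", 0.30,
    "tap_spatial_sd",  5,     9,      "lognormal", 0.25,
    "path_tremor_amp", 1.0,   8.0,    "lognormal", 0.35,
    "vstm_hit",        0.90,  0.85,   "beta_sd",   0.05,
    "sdmt_completed",  40,    32,     "normal",    3,
    "sdmt_accuracy",   0.97,  0.93,   "beta_sd",   0.03
  )
}

#' Specify a synthetic cohort
#'
#' @param n_pd,n_hc participants per group
#' @param n_clinic_visits,n_home_visits sessions per participant by
#'   environment (defaults mirror a one-year design: 6 clinic visits at
#'   months 0/1/3/6/9/12 and 24 biweekly home visits)
#' @param effect_scale 0 = null cohort (groups exchangeable), 1 = the
#'   "strong" preset group separation
#' @param subject_sd between-subject random-effect scale (SD of the
#'   per-subject multiplicative log-normal factor applied to every
#'   generator parameter, shared across that subject's sessions)
#' @param session_sd within-subject session-to-session parameter noise
#' @param env_shift multiplicative shift applied to motor parameters in
#'   home sessions (0 = environments generated identically)
#' @param battery assessments to generate (subset of
#'   [assessment_registry()])
#' @param motion_rate,audio_rate sampling rates in Hz
#' @param tremor_duration,audio_duration record lengths in seconds
#' @param gait_steps steps per synthetic walking bout
#' @param n_taps taps per hand per session
#' @param seed integer seed; generation is a pure function of (spec, seed)
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_pd = 82, n_hc = 50, n_clinic_visits = 6,
                        n_home_visits = 24, effect_scale = 1,
                        subject_sd = 0.15, session_sd = 0.08,
                        env_shift = 0, battery = assessment_registry(),
                        motion_rate = 100, audio_rate = 32000,
                        tremor_duration = 10, audio_duration = 15,
                        gait_steps = 54, n_taps = 60, seed = 1) {
  stopifnot(n_pd >= 1, n_hc >= 1, effect_scale >= 0, subject_sd >= 0)
  battery <- match.arg(battery, ASSESSMENTS, several.ok = TRUE)
  structure(as.list(environment()), class = "cohort_spec")
}

draw_param <- function(row, scale, n) {
  m <- row$hc + scale * (row$pd - row$hc)
  switch(row$dist,
    lognormal = rlnorm(n, log(m), row$sdlog_or_sd),
    normal = rnorm(n, m, row$sdlog_or_sd),
    uniform1.5 = runif(n, m - 1.5, m + 1.5),
    beta_sd = pmin(pmax(rnorm(n, m, row$sdlog_or_sd), 0.01), 0.999)
  )
}

#' Generate a synthetic study cohort
#'
#' Each participant receives clinic and home sessions; group differences
#' enter through shifted parameter distributions (not deterministic
#' labels), so classifiers face realistic overlap; per-subject
#' multiplicative random effects are shared across sessions, inducing
#' within-subject correlation.
#'
#' @param spec a [cohort_spec()]
#' @return list with `sessions` (list of `session_record`) and `truth`
#'   (tibble of injected per-session parameters)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pt <- param_table()
  ids <- c(sprintf("PD%03d", seq_len(spec$n_pd)),
           sprintf("HC%03d", seq_len(spec$n_hc)))
  groups <- c(rep("PD", spec$n_pd), rep("HC", spec$n_hc))
  clinic_days <- c(0, 30, 90, 180, 270, 360)
  clinic_days <- clinic_days[seq_len(min(spec$n_clinic_visits, 6))]
  if (spec$n_clinic_visits > 6) {
    clinic_days <- c(clinic_days, 360 + 30 * seq_len(spec$n_clinic_visits - 6))
  }
  home_days <- 14 * seq_len(spec$n_home_visits)

  # participant-level parameter means (group effect + subject random effect)
  subj_params <- with_seed_(child_seed(spec$seed, "subjects"), {
    out <- list()
    for (i in seq_along(ids)) {
      scale <- if (groups[i] == "PD") spec$effect_scale else 0
      p <- numeric(nrow(pt))
      names(p) <- pt$param
      for (j in seq_len(nrow(pt))) p[j] <- draw_param(pt[j, ], scale, 1)
      re <- exp(rnorm(nrow(pt), 0, spec$subject_sd))
      out[[ids[i]]] <- p * re
    }
    out
  })

  sessions <- list()
  truth <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    visits <- tibble::tibble(
      environment = c(rep("clinic", length(clinic_days)),
                      rep("home", length(home_days))),
      day = c(clinic_days, home_days)
    )
    for (v in seq_len(nrow(visits))) {
      env <- visits$environment[v]
      sseed <- child_seed(spec$seed, id, v)
      p <- with_seed_(child_seed(sseed, "params"), {
        pp <- subj_params[[id]] * exp(rnorm(nrow(pt), 0, spec$session_sd))
        if (env == "home" && spec$env_shift != 0) {
          motor <- c("tremor_amp", "arm_swing_amp", "timing_jitter",
                     "jitter_pct", "tap_sd_iti", "path_tremor_amp")
          pp[motor] <- pp[motor] * (1 + spec$env_shift)
        }
        pp
      })
      p["tremor_freq"] <- min(max(p["tremor_freq"], 4), 10)
      p["vstm_hit"] <- min(max(p["vstm_hit"], 0.01), 0.999)
      p["sdmt_accuracy"] <- min(max(p["sdmt_accuracy"], 0.01), 0.999)
      payloads <- generate_payloads(p, spec, sseed)
      sessions[[length(sessions) + 1]] <- session_record(
        participant_id = id, group = groups[i], environment = env,
        visit_index = v - 1L, visit_time = visits$day[v], payloads = payloads
      )
      truth[[length(truth) + 1]] <- tibble::tibble(
        participant_id = id, group = groups[i], environment = env,
        visit_index = v - 1L, !!!as.list(p)
      )
    }
  }
  list(sessions = sessions, truth = dplyr::bind_rows(truth))
}

generate_payloads <- function(p, spec, sseed) {
  b <- spec$battery
  pay <- list()
  if ("tremor" %in% b) {
    pay$tremor <- list(
      postural = synth_tremor_trace(p["tremor_amp"], p["tremor_freq"],
                                    duration = spec$tremor_duration,
                                    rate = spec$motion_rate,
                                    seed = child_seed(sseed, "trem_post")),
      resting = synth_tremor_trace(p["tremor_amp"] * 0.8, p["tremor_freq"],
                                   duration = spec$tremor_duration,
                                   rate = spec$motion_rate,
                                   seed = child_seed(sseed, "trem_rest"))
    )
  }
  if ("gait_balance" %in% b) {
    gait <- synth_gait_trace(p["cadence"], spec$gait_steps,
                             arm_swing_amp = p["arm_swing_amp"],
                             timing_jitter_sd = p["timing_jitter"],
                             rate = spec$motion_rate,
                             seed = child_seed(sseed, "gait"))
    balance <- list(
      watch = synth_tremor_trace(p["tremor_amp"] * 0.5, p["tremor_freq"],
                                 duration = max(5.5, spec$tremor_duration),
                                 rate = spec$motion_rate,
                                 seed = child_seed(sseed, "bal_w")),
      phone = synth_tremor_trace(p["tremor_amp"] * 0.2, p["tremor_freq"],
                                 duration = max(5.5, spec$tremor_duration),
                                 rate = spec$motion_rate, device = "phone",
                                 seed = child_seed(sseed, "bal_p"))
    )
    pay$gait_balance <- list(gait = list(watch = gait$watch, phone = gait$phone),
                             balance = balance,
                             step_times = attr(gait, "step_times"))
  }
  if ("phonation" %in% b) {
    pay$phonation <- synth_voice(p["f0"], p["jitter_pct"], p["shimmer_db"],
                                 p["hnr_db"], duration = spec$audio_duration,
                                 rate = spec$audio_rate,
                                 seed = child_seed(sseed, "phon"))
  }
  if ("articulation" %in% b) {
    clip <- synth_voice(p["f0"], p["jitter_pct"], p["shimmer_db"],
                        p["hnr_db"], duration = spec$audio_duration,
                        rate = spec$audio_rate,
                        seed = child_seed(sseed, "artic"))
    # syllable repetition emulated as slow amplitude modulation of the train
    tt <- seq_along(clip$samples) / clip$rate
    clip$samples <- clip$samples * (0.7 + 0.3 * sin(2 * pi * 2.5 * tt))
    pay$articulation <- clip
  }
  if ("finger_tapping" %in% b) {
    pay$finger_tapping <- list(
      dominant = synth_taps(p["tap_mean_iti"], p["tap_sd_iti"], spec$n_taps,
                            p["tap_spatial_sd"], hand = "dominant",
                            seed = child_seed(sseed, "tapd")),
      nondominant = synth_taps(p["tap_mean_iti"] * 1.1, p["tap_sd_iti"] * 1.1,
                               spec$n_taps, p["tap_spatial_sd"] * 1.1,
                               hand = "nondominant",
                               seed = child_seed(sseed, "tapn"))
    )
  }
  if ("fine_motor" %in% b) {
    n_dom <- max(1L, round(12 * 200 / p["tap_mean_iti"]))
    n_nondom <- max(1L, round(n_dom * 0.9))
    pay$fine_motor <- list(
      dominant = list(log = synth_path("finemotor", p["path_tremor_amp"],
                                       seed = child_seed(sseed, "fmd")),
                      n_completed = n_dom),
      nondominant = list(log = synth_path("finemotor", p["path_tremor_amp"] * 1.2,
                                          seed = child_seed(sseed, "fmn")),
                         n_completed = n_nondom)
    )
  }
  if ("trails" %in% b) {
    pay$trails <- list(
      A = synth_path("trails", p["path_tremor_amp"],
                     seed = child_seed(sseed, "trA")),
      B = synth_path("trails", p["path_tremor_amp"],
                     speed = 450, seed = child_seed(sseed, "trB"))
    )
  }
  if ("vstm" %in% b) {
    pay$vstm <- synth_trials("vstm", hit_rate = p["vstm_hit"], fa_rate = 0.1,
                             seed = child_seed(sseed, "vstm"))
  }
  if ("sdmt" %in% b) {
    pay$sdmt <- synth_trials("sdmt", n_completed = max(1L, round(p["sdmt_completed"])),
                             accuracy = p["sdmt_accuracy"],
                             seed = child_seed(sseed, "sdmt"))
  }
  pay
}

#' Construct a session record
#'
#' One participant-visit bundle: group and environment labels, visit
#' bookkeeping and the per-assessment raw payloads.
#'
#' @param participant_id participant identifier
#' @param group `"PD"` or `"HC"`
#' @param environment `"clinic"` or `"home"`
#' @param visit_index zero-based visit counter
#' @param visit_time study day of the visit
#' @param payloads named list keyed by assessment name
#' @return a `session_record`
#' @export
session_record <- function(participant_id, group, environment, visit_index,
                           visit_time, payloads = list()) {
  group <- match.arg(group, c("PD", "HC"))
  environment <- match.arg(environment, c("clinic", "home"))
  stopifnot(visit_index >= 0)
  bad <- setdiff(names(payloads), ASSESSMENTS)
  if (length(bad) > 0) {
    stop("unknown assessment(s): ", paste(bad, collapse = ", "))
  }
  structure(list(participant_id = participant_id, group = group,
                 environment = environment, visit_index = as.integer(visit_index),
                 visit_time = visit_time, payloads = payloads),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s [%s] %s visit %d (day %s): %d payload(s)\n",
              x$participant_id, x$group, x$environment, x$visit_index,
              format(x$visit_time), length(x$payloads)))
  invisible(x)
}
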