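# File dialects: sensor CSV (t, ax, ay, az), touch CSV (t, x, y, phase,
# hand, target_id[, duration, angle]), mono PCM16 WAV for audio, YAML
# session manifests, CSV feature matrices and JSON results.

#' Read a triaxial accelerometer CSV
#'
#' Columns `t, ax, ay, az`; timestamps in seconds. Rows with non-numeric
#' or missing values are dropped and counted (see the trace's `n_dropped`
#' attribute).
#'
#' @param path CSV file
#' @param device,frame trace metadata
#' @return a `motion_trace`
#' @export
read_motion_csv <- function(path, device = "watch", frame = "device") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed sensor CSV ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  motion_trace(df$t, df$ax, df$ay, df$az, device = device, frame = frame)
}

#' @rdname read_motion_csv
#' @param trace a `motion_trace`
#' @export
write_motion_csv <- function(trace, path) {
  readr::write_csv(tibble::tibble(t = trace$t, ax = trace$ax,
                                  ay = trace$ay, az = trace$az), path)
  invisible(path)
}

#' Read / write a touch-event CSV
#'
#' Columns `t` (ms, non-decreasing), `x`, `y` (px), `phase`
#' (down/move/up), `hand`, `target_id`; optional `duration` and `angle`.
#'
#' @param path CSV file
#' @return a `touch_log` tibble
#' @export
read_touch_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t", "x", "y", "phase", "hand", "target_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed touch CSV ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.unsorted(df$t)) stop("touch timestamps must be non-decreasing")
  structure(df, class = c("touch_log", class(df)))
}

#' @rdname read_touch_csv
#' @param log a `touch_log`
#' @export
write_touch_csv <- function(log, path) {
  readr::write_csv(as.data.frame(log), path)
  invisible(path)
}

#' Read a mono PCM16 WAV file
#'
#' Minimal RIFF/WAVE reader for the canonical 16-bit mono PCM layout.
#'
#' @param path WAV file
#' @return an `audio_clip` with samples in \[-1, 1\]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("unreadable WAV (no RIFF header): ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("unreadable WAV (no WAVE tag): ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(rate) || is.null(samples)) stop("unreadable WAV: ", path)
  if (!identical(channels, 1L)) stop("only mono WAV is supported: ", path)
  if (!identical(bits, 16L)) stop("only 16-bit PCM WAV is supported: ", path)
  audio_clip(samples / 32768, rate)
}

#' @rdname read_wav
#' @param clip an `audio_clip`
#' @export
write_wav <- function(clip, path) {
  s <- pmax(pmin(clip$samples, 1), -1)
  pcm <- as.integer(pmin(round(s * 32768), 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(clip$rate), con, 4, endian = "little")
  writeBin(as.integer(clip$rate * 2), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")          # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Write a feature matrix to CSV
#'
#' Key columns first, then feature columns. Round-tripping through
#' [read_feature_matrix()] reproduces names bit-exactly and values to
#' full double precision.
#'
#' @param matrix tibble of features with key columns
#' @param path CSV file
#' @export
write_feature_matrix <- function(matrix, path) {
  feat <- names(matrix)[!names(matrix) %in% session_key_cols()]
  if (anyDuplicated(feat)) {
    stop("duplicate feature name(s): ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  }
  keys <- intersect(session_key_cols(), names(matrix))
  if (all(c("participant_id", "visit_index") %in% keys)) {
    key <- paste(matrix$participant_id, matrix$visit_index)
    if (anyDuplicated(key)) stop("duplicate (participant, session) row keys")
  }
  readr::write_csv(matrix, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  guess_max = 10000)
}

#' Read a session from a YAML manifest
#'
#' The manifest names the participant, group, environment and visit, and
#' maps assessment names to payload files (relative to the manifest).
#' Missing assessments are recorded as absent — not errors — and logged.
#'
#' @param manifest_path YAML file
#' @return a `session_record`
#' @export
read_session <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  payloads <- list()
  absent <- character(0)
  for (a in names(man$payloads %||% list())) {
    entry <- man$payloads[[a]]
    loaded <- tryCatch(load_payload(a, entry, base), error = function(e) {
      stop("failed loading ", a, " payload: ", conditionMessage(e))
    })
    if (is.null(loaded)) absent <- c(absent, a) else payloads[[a]] <- loaded
  }
  missing_assessments <- setdiff(ASSESSMENTS, names(payloads))
  if (length(missing_assessments) > 0) {
    message("session ", man$participant_id, ": ",
            length(missing_assessments), " assessment(s) absent: ",
            paste(missing_assessments, collapse = ", "))
  }
  session_record(man$participant_id, man$group, man$environment,
                 man$visit_index %||% 0, man$visit_time %||% 0, payloads)
}

resolve_file <- function(base, f) {
  p <- file.path(base, f)
  if (!file.exists(p)) return(NULL)
  p
}

load_payload <- function(assessment, entry, base) {
  get_file <- function(f) {
    p <- resolve_file(base, f)
    if (is.null(p)) stop("payload file not found: ", f)
    p
  }
  any_missing <- function(fs) any(vapply(fs, function(f) {
    is.null(resolve_file(base, f))
  }, logical(1)))
  switch(assessment,
    tremor = {
      if (any_missing(c(entry$postural, entry$resting))) return(NULL)
      list(postural = read_motion_csv(get_file(entry$postural), "watch"),
           resting = read_motion_csv(get_file(entry$resting), "watch"))
    },
    gait_balance = {
      fs <- c(entry$gait_watch, entry$gait_phone,
              entry$balance_watch, entry$balance_phone)
      if (any_missing(fs)) return(NULL)
      list(gait = list(watch = read_motion_csv(get_file(entry$gait_watch), "watch"),
                       phone = read_motion_csv(get_file(entry$gait_phone), "phone")),
           balance = list(watch = read_motion_csv(get_file(entry$balance_watch), "watch"),
                          phone = read_motion_csv(get_file(entry$balance_phone), "phone")))
    },
    phonation = ,
    articulation = {
      if (any_missing(entry$wav)) return(NULL)
      read_wav(get_file(entry$wav))
    },
    finger_tapping = {
      if (any_missing(c(entry$dominant, entry$nondominant))) return(NULL)
      # the task's two target locations are fixed by the battery layout
      targets <- data.frame(target_id = c(1, 2), x = c(120, 260), y = c(420, 420))
      wt <- function(f) {
        log <- read_touch_csv(get_file(f))
        attr(log, "targets") <- targets
        log
      }
      list(dominant = wt(entry$dominant), nondominant = wt(entry$nondominant))
    },
    trails = {
      if (any_missing(c(entry$A, entry$B))) return(NULL)
      ideal <- idealized_path(cbind(x = c(60, 300, 120, 330, 80, 280),
                                    y = c(80, 140, 300, 380, 500, 560)))
      wt <- function(f) {
        log <- read_touch_csv(get_file(f))
        attr(log, "ideal") <- ideal
        log
      }
      list(A = wt(entry$A), B = wt(entry$B))
    },
    fine_motor = {
      if (any_missing(c(entry$dominant, entry$nondominant))) return(NULL)
      ideal <- idealized_path(cbind(x = c(80, 300), y = c(200, 420)))
      wt <- function(f) {
        log <- read_touch_csv(get_file(f))
        attr(log, "ideal") <- ideal
        attr(log, "ideal_rotation") <- 90
        log
      }
      list(dominant = list(log = wt(entry$dominant),
                           n_completed = entry$n_dominant),
           nondominant = list(log = wt(entry$nondominant),
                              n_completed = entry$n_nondominant))
    },
    vstm = ,
    sdmt = {
      if (any_missing(entry$trials)) return(NULL)
      readr::read_csv(get_file(entry$trials), show_col_types = FALSE)
    },
    stop("unknown assessment: ", assessment)
  )
}

#' Write a generated cohort to a directory tree
#'
#' One directory per session holding the payload files in the documented
#' dialects plus a `manifest.yaml`; the injected ground truth is written
#' to `truth.json` at the root.
#'
#' @param cohort list from [generate_cohort()]
#' @param dir output directory
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions) {
    sdir <- file.path(dir, sprintf("%s_v%02d", s$participant_id, s$visit_index))
    dir.create(sdir, showWarnings = FALSE)
    man <- list(participant_id = s$participant_id, group = s$group,
                environment = s$environment, visit_index = s$visit_index,
                visit_time = s$visit_time, payloads = list())
    p <- s$payloads
    if (!is.null(p$tremor)) {
      write_motion_csv(p$tremor$postural, file.path(sdir, "tremor_postural.csv"))
      write_motion_csv(p$tremor$resting, file.path(sdir, "tremor_resting.csv"))
      man$payloads$tremor <- list(postural = "tremor_postural.csv",
                                  resting = "tremor_resting.csv")
    }
    if (!is.null(p$gait_balance)) {
      gb <- p$gait_balance
      write_motion_csv(gb$gait$watch, file.path(sdir, "gait_watch.csv"))
      write_motion_csv(gb$gait$phone, file.path(sdir, "gait_phone.csv"))
      write_motion_csv(gb$balance$watch, file.path(sdir, "balance_watch.csv"))
      write_motion_csv(gb$balance$phone, file.path(sdir, "balance_phone.csv"))
      man$payloads$gait_balance <- list(gait_watch = "gait_watch.csv",
                                        gait_phone = "gait_phone.csv",
                                        balance_watch = "balance_watch.csv",
                                        balance_phone = "balance_phone.csv")
    }
    for (voice in c("phonation", "articulation")) {
      if (!is.null(p[[voice]])) {
        f <- paste0(voice, ".wav")
        write_wav(p[[voice]], file.path(sdir, f))
        man$payloads[[voice]] <- list(wav = f)
      }
    }
    if (!is.null(p$finger_tapping)) {
      write_touch_csv(p$finger_tapping$dominant, file.path(sdir, "tap_dom.csv"))
      write_touch_csv(p$finger_tapping$nondominant, file.path(sdir, "tap_nondom.csv"))
      man$payloads$finger_tapping <- list(dominant = "tap_dom.csv",
                                          nondominant = "tap_nondom.csv")
    }
    if (!is.null(p$trails)) {
      write_touch_csv(p$trails$A, file.path(sdir, "trails_a.csv"))
      write_touch_csv(p$trails$B, file.path(sdir, "trails_b.csv"))
      man$payloads$trails <- list(A = "trails_a.csv", B = "trails_b.csv")
    }
    if (!is.null(p$fine_motor)) {
      write_touch_csv(p$fine_motor$dominant$log, file.path(sdir, "fm_dom.csv"))
      write_touch_csv(p$fine_motor$nondominant$log, file.path(sdir, "fm_nondom.csv"))
      man$payloads$fine_motor <- list(
        dominant = "fm_dom.csv", nondominant = "fm_nondom.csv",
        n_dominant = p$fine_motor$dominant$n_completed,
        n_nondominant = p$fine_motor$nondominant$n_completed)
    }
    for (cg in c("vstm", "sdmt")) {
      if (!is.null(p[[cg]])) {
        f <- paste0(cg, "_trials.csv")
        readr::write_csv(p[[cg]], file.path(sdir, f))
        man$payloads[[cg]] <- list(trials = f)
      }
    }
    yaml::write_yaml(man, file.path(sdir, "manifest.yaml"))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}
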