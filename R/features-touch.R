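# Touch-stream and trial-table features: finger tapping (28), fine motor
# (19), trails (12), SDMT (2) and VSTM (2). Irregular touch-event series
# are linearly resampled to a uniform 60 Hz clock before any spectral
# analysis.

TOUCH_FS <- 60

# Tremor-band energy of an irregular touch tracing: resample to 60 Hz and
# remove the linear drawing trend so the slow traversal of the screen does
# not leak into the 4-10 Hz band.
touch_band_energy <- function(t_ms, x, lo = 4, hi = 10) {
  if (length(t_ms) < 8 || diff(range(t_ms)) <= 0) return(NA_real_)
  xx <- resample_uniform(t_ms / 1000, x, TOUCH_FS)
  if (length(xx) < 8) return(NA_real_)
  idx <- seq_along(xx)
  xx <- stats::lm.fit(cbind(1, idx), xx)$residuals
  psd <- welch_psd(xx, TOUCH_FS)
  band_energy(psd, lo, hi)
}

tapping_hand_names <- function() {
  c("alternating", "total", "ratio",
    "duration.median", "duration.iqr", "distance.median", "distance.iqr",
    "asynchrony.median", "asynchrony.iqr", "iti.median", "iti.iqr",
    "spatialvar.vertical.iqr", "spatialvar.horizontal.iqr", "peak_freq")
}

tapping_hand_features <- function(log) {
  nm <- tapping_hand_names()
  if (is.null(log)) return(na_like(nm))
  downs <- log[log$phase == "down", ]
  n <- nrow(downs)
  if (n < 3) return(na_like(nm))
  targets <- attr(log, "targets")
  alternating <- 1 + sum(diff(downs$target_id) != 0)
  durations <- if ("duration" %in% names(downs)) downs$duration else {
    ups <- log[log$phase == "up", ]
    ups$t[seq_len(n)] - downs$t
  }
  dist <- if (!is.null(targets)) {
    apply(cbind(downs$x, downs$y), 1, function(pp) {
      min(sqrt((targets$x - pp[1])^2 + (targets$y - pp[2])^2))
    })
  } else rep(NA_real_, n)
  # onset asynchrony: absolute deviation from the best-fit isochronous grid
  idx <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, idx), downs$t)
  asyn <- abs(fit$residuals)
  iti <- diff(downs$t)
  # spatial variance over sliding 10-tap windows
  win <- 10
  if (n >= win) {
    vx <- vapply(seq_len(n - win + 1), function(k) var(downs$x[k:(k + win - 1)]),
                 numeric(1))
    vy <- vapply(seq_len(n - win + 1), function(k) var(downs$y[k:(k + win - 1)]),
                 numeric(1))
  } else {
    vx <- var(downs$x); vy <- var(downs$y)
  }
  # peak spectral frequency of the binarized tap-onset time series
  dur_s <- diff(range(downs$t)) / 1000
  peak_freq <- NA_real_
  if (dur_s > 1) {
    tt <- seq(0, dur_s, by = 1 / TOUCH_FS)
    z <- numeric(length(tt))
    z[pmin(length(tt), floor((downs$t - downs$t[1]) / 1000 * TOUCH_FS) + 1)] <- 1
    psd <- welch_psd(z, TOUCH_FS, seg_len = length(z))
    pk <- psd[psd$frequency > 0.5, ]
    peak_freq <- pk$frequency[which.max(pk$power)]
  }
  setNames(c(alternating, n, alternating / n,
             median(durations), iqr_(durations),
             median(dist), iqr_(dist),
             median(asyn), iqr_(asyn),
             median(iti), iqr_(iti),
             iqr_(vy), iqr_(vx), peak_freq), nm)
}

#' Finger-tapping features
#'
#' Twenty-eight features, fourteen per hand: alternating-tap count, total
#' taps and their ratio; median and IQR of tap duration, tap-to-target
#' distance, tap onset asynchrony (deviation from the best-fit isochronous
#' grid) and inter-tap interval; IQR of the sliding-window spatial variance
#' in the vertical and horizontal screen dimensions; and the peak spectral
#' frequency of the binarized tap-onset series.
#'
#' @param payload list with `dominant` and `nondominant` `touch_log`s
#' @return named numeric vector of length 28
#' @export
tapping_features <- function(payload) {
  out <- c()
  for (hand in c("dominant", "nondominant")) {
    v <- tapping_hand_features(payload[[hand]])
    out <- c(out, setNames(v, paste0("finger_tapping.", hand, ".", names(v))))
  }
  out
}

finemotor_hand_names <- function() {
  c("pathlen", "pathlen_ratio", "speed", "rotation", "rotation_ratio",
    "rotation_speed", "band4_10.vertical", "band4_10.horizontal")
}

finemotor_hand_features <- function(entry) {
  nm <- finemotor_hand_names()
  if (is.null(entry)) return(na_like(nm))
  log <- entry$log
  ideal <- attr(log, "ideal")
  ideal_rot <- attr(log, "ideal_rotation")
  pl <- path_length(cbind(log$x, log$y))
  dur_ms <- diff(range(log$t))
  rot <- if ("angle" %in% names(log)) sum(abs(diff(log$angle))) else NA_real_
  setNames(c(pl,
             pl / ideal$length,
             pl / dur_ms,
             rot,
             if (is.na(rot)) NA_real_ else rot / ideal_rot,
             if (is.na(rot)) NA_real_ else rot / dur_ms,
             touch_band_energy(log$t, log$y),
             touch_band_energy(log$t, log$x)), nm)
}

#' Fine-motor (drag-and-rotate) features
#'
#' Nineteen features: totals completed with each hand and their ratio,
#' plus per hand: total path length, path-length ratio to the idealized
#' path, movement speed (px/ms), total rotation, rotation ratio to the
#' idealized rotation, rotation speed (deg/ms), and 4-10 Hz spectral
#' energy of the vertical and horizontal position tracings.
#'
#' @param payload list with `dominant`/`nondominant`, each holding `log`
#'   (a `touch_log` with an `angle` column) and `n_completed`
#' @return named numeric vector of length 19
#' @export
finemotor_features <- function(payload) {
  nd <- payload$dominant$n_completed
  nn <- payload$nondominant$n_completed
  out <- c("fine_motor.summary.dominant_total" = if (is.null(nd)) NA_real_ else nd,
           "fine_motor.summary.nondominant_total" = if (is.null(nn)) NA_real_ else nn,
           "fine_motor.summary.ratio" =
             if (is.null(nd) || is.null(nn) || nn == 0) NA_real_ else nd / nn)
  for (hand in c("dominant", "nondominant")) {
    v <- finemotor_hand_features(payload[[hand]])
    out <- c(out, setNames(v, paste0("fine_motor.", hand, ".", names(v))))
  }
  out
}

#' Distance from points to a piecewise-linear path
#'
#' Minimum Euclidean distance from each point to any segment of the path
#' (perpendicular foot where it falls inside the segment, nearest endpoint
#' otherwise).
#'
#' @param points two-column matrix of points
#' @param ideal an `idealized_path`
#' @return numeric vector of distances
#' @export
point_to_path_distance <- function(points, ideal) {
  pts <- as.matrix(points)
  tg <- ideal$targets
  nseg <- nrow(tg) - 1
  dmin <- rep(Inf, nrow(pts))
  for (k in seq_len(nseg)) {
    a <- tg[k, ]; b <- tg[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    dx <- pts[, 1] - (a[1] + tt * ab[1])
    dy <- pts[, 2] - (a[2] + tt * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

trails_subtask_names <- function() {
  c("completion_time", "pathlen", "rmse",
    "band4_10.vertical", "band4_10.horizontal", "band4_10.residual")
}

trails_subtask_features <- function(log) {
  nm <- trails_subtask_names()
  if (is.null(log)) return(na_like(nm))
  ideal <- attr(log, "ideal")
  d <- point_to_path_distance(cbind(log$x, log$y), ideal)
  setNames(c(diff(range(log$t)) / 1000,
             path_length(cbind(log$x, log$y)),
             sqrt(mean(d^2)),
             touch_band_energy(log$t, log$y),
             touch_band_energy(log$t, log$x),
             touch_band_energy(log$t, d)), nm)
}

#' Trail-making features
#'
#' Twelve features, six per sub-task (A: numeric order; B: alternating
#' number-letter order): completion time, total reconstructed path length,
#' RMSE between the reconstructed and idealized paths, and 4-10 Hz
#' spectral energy of the vertical tracing, the horizontal tracing and the
#' residual-error series.
#'
#' @param payload list with `A` and `B` `touch_log`s carrying an `ideal`
#'   attribute
#' @return named numeric vector of length 12
#' @export
trails_features <- function(payload) {
  out <- c()
  for (sub in c("A", "B")) {
    v <- trails_subtask_features(payload[[sub]])
    out <- c(out, setNames(v, paste0("trails.", tolower(sub), ".", names(v))))
  }
  out
}

#' Visual short-term memory features
#'
#' Mean response accuracy and working-memory capacity
#' K = set size x (hit rate - false-alarm rate) for the single-probe
#' change-detection design (set size 4).
#'
#' @param trials tibble with `set_size`, `change`, `response_change`,
#'   `correct`
#' @return named numeric vector of length 2
#' @export
vstm_features <- function(trials) {
  nm <- c("vstm.accuracy", "vstm.k")
  if (is.null(trials) || nrow(trials) == 0) return(na_like(nm))
  hit <- mean(trials$response_change[trials$change])
  fa <- mean(trials$response_change[!trials$change])
  k <- trials$set_size[1] * (hit - fa)
  setNames(c(mean(trials$correct), k), nm)
}

#' Symbol-digit modalities features
#'
#' Total completed symbol-digit pairs and mean response accuracy.
#'
#' @param trials tibble with one row per completed pair and a `correct`
#'   column
#' @return named numeric vector of length 2
#' @export
sdmt_features <- function(trials) {
  nm <- c("sdmt.total_completed", "sdmt.accuracy")
  if (is.null(trials) || nrow(trials) == 0) return(na_like(nm))
  setNames(c(nrow(trials), mean(trials$correct)), nm)
}
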