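# Tremor and gait/balance feature catalog. Per accelerometer axis the
# catalog computes 20 univariate time-domain and 49 univariate
# frequency-domain features; per kinematic stack 24 multivariate
# time-domain features; per device pair 285 spectral coherence features;
# per axis/device 51 gait-event features. The per-assessment totals are
# fixed by construction: 231 unique features per tremor sub-task (462
# total) and 1053 per gait/balance task (2106 total).

TIME_STATS8 <- c("mean", "median", "q1", "q3", "iqr", "sd", "kurtosis", "skewness")
TREMOR_BANDS <- list(c(3.5, 4.5), c(4.5, 5.5), c(5.5, 6.5), c(6.5, 7.5),
                     c(7.5, 8.5), c(8.5, 9.5), c(9.5, 10.5), c(4, 10))
TREMOR_BAND_NAMES <- c("3.5_4.5", "4.5_5.5", "5.5_6.5", "6.5_7.5",
                       "7.5_8.5", "8.5_9.5", "9.5_10.5", "4_10")

#' Univariate time-domain features of one kinematic axis
#'
#' Twenty features: zero-cross rate of the mean-centered acceleration;
#' eight summary statistics of the inter-cross interval distribution; SD
#' and IQR of raw acceleration; six summary statistics of integrated
#' velocity; and the total path length of acceleration, velocity and
#' position.
#'
#' @param accel,vel,pos one axis of the kinematic stack
#' @param t timestamps in seconds
#' @return named numeric vector of length 20
#' @export
univariate_time_features <- function(accel, vel, pos, t) {
  if (length(accel) < 3) stop("series shorter than 3 samples")
  xc <- accel - mean(accel)
  s <- sign(xc)
  s[s == 0] <- 1 # a touch of zero counts at most once, never twice
  cross_idx <- which(diff(s) != 0)
  cross_times <- t[cross_idx]
  duration <- diff(range(t))
  ic <- diff(cross_times) * 1000 # ms
  ics <- stats8(ic)[c("median", "mean", "q1", "q3", "iqr", "sd", "kurtosis", "skewness")]
  vstats <- c(mean = mean(vel), median = median(vel), sd = sd(vel),
              q1 = q1(vel), q3 = q3(vel), iqr = iqr_(vel))
  c(zcr = length(cross_idx) / duration,
    setNames(ics, paste0("icross.", names(ics))),
    accel.sd = sd(accel), accel.iqr = iqr_(accel),
    setNames(vstats, paste0("vel.", names(vstats))),
    pathlen.accel = path_length(accel),
    pathlen.vel = path_length(vel),
    pathlen.pos = path_length(pos))
}

#' Multivariate time-domain features of a kinematic stack
#'
#' Total path length and convex hull area for each unique axis combination
#' (x-y, x-z, y-z, x-y-z) of acceleration, velocity and position: 24
#' features. Two-dimensional combinations use polygon hull area; the
#' three-axis combination uses the hull's surface area.
#'
#' @param stack a `kinematic_stack` from [integrate_kinematics()]
#' @return named numeric vector of length 24
#' @export
multivariate_time_features <- function(stack) {
  out <- c()
  combos <- list(xy = c("x", "y"), xz = c("x", "z"), yz = c("y", "z"),
                 xyz = c("x", "y", "z"))
  for (sig in c("accel", "velocity", "position")) {
    m <- as.matrix(stack[[sig]][, c("x", "y", "z")])
    sname <- c(accel = "accel", velocity = "vel", position = "pos")[sig]
    for (cn in names(combos)) {
      sub <- m[, combos[[cn]], drop = FALSE]
      hull <- if (ncol(sub) == 2) hull_area_2d(sub) else hull_surface_area_3d(sub)
      out <- c(out,
               setNames(path_length(sub), paste0(sname, ".", cn, ".pathlen")),
               setNames(hull, paste0(sname, ".", cn, ".hull")))
    }
  }
  out
}

#' Univariate frequency-domain features of one acceleration axis
#'
#' Forty-nine features from the Welch PSD: eight tremor-band energies
#' (seven 1-Hz bands spanning 3.5-10.5 Hz plus the 4-10 Hz band), spectral
#' roll-off at 1/25/50/75/99%, MFCC 1-16 computed over 0-49 Hz, and five
#' distributional statistics (entropy, SD, kurtosis, skewness, flatness)
#' of four spectral views: the full 0-49 Hz spectrum, the 4-10 Hz band,
#' the spectrum outside 4-10 Hz, and the in-band spectrum normalized by
#' total out-of-band energy.
#'
#' @param x acceleration axis series
#' @param fs sampling rate in Hz
#' @return named numeric vector of length 49
#' @export
univariate_frequency_features <- function(x, fs) {
  psd <- welch_psd(x, fs)
  psd <- psd[psd$frequency <= 49, ]
  bands <- vapply(TREMOR_BANDS, function(b) band_energy(psd, b[1], b[2]), numeric(1))
  names(bands) <- paste0("band.", TREMOR_BAND_NAMES)
  ro <- vapply(c(1, 25, 50, 75, 99), function(p) spectral_rolloff(psd, p), numeric(1))
  names(ro) <- paste0("rolloff.p", c(1, 25, 50, 75, 99))
  mf <- mfcc_from_psd(psd, n_coef = 16, n_filters = 32, fmax = 49)
  inband <- psd$frequency >= 4 & psd$frequency < 10
  out_e <- sum(psd$power[!inband]) * (psd$frequency[2] - psd$frequency[1])
  views <- list(total = psd$power,
                inband = psd$power[inband],
                outband = psd$power[!inband],
                ratio = psd$power[inband] / max(out_e, 1e-300))
  vs <- unlist(lapply(names(views), function(v) {
    setNames(spectral_view_stats(views[[v]]),
             paste0(v, ".", c("entropy", "sd", "kurtosis", "skewness", "flatness")))
  }))
  c(bands, ro, mf, vs)
}

#' Spectral coherence features between synchronized devices
#'
#' Nineteen features for each of the 15 unordered pairs among the six
#' acceleration channels (3 watch + 3 phone): peak-coherence frequency,
#' total coherence (sum over frequency bins), and coherence sampled at
#' 1-10, 15, 20, 25, 30, 35, 40 and 45 Hz. 285 features in total.
#'
#' @param watch,phone synchronized `motion_trace` objects on a common clock
#' @return named numeric vector of length 285
#' @export
coherence_features <- function(watch, phone) {
  if (nrow(watch) != nrow(phone)) stop("traces must be synchronized first")
  fs <- sampling_rate(watch$t)
  chans <- list(watch.x = watch$ax, watch.y = watch$ay, watch.z = watch$az,
                phone.x = phone$ax, phone.y = phone$ay, phone.z = phone$az)
  qfreq <- c(1:10, 15, 20, 25, 30, 35, 40, 45)
  nm <- names(chans)
  out <- c()
  for (i in 1:5) {
    for (j in (i + 1):6) {
      coh <- msc_coherence(chans[[i]], chans[[j]], fs)
      pk <- coh$frequency[which.max(coh$coherence)]
      at <- vapply(qfreq, function(f) {
        coh$coherence[which.min(abs(coh$frequency - f))]
      }, numeric(1))
      pair <- paste0(nm[i], "_", nm[j])
      out <- c(out, setNames(c(pk, sum(coh$coherence), at),
                             paste0(pair, ".", c("peak_freq", "total",
                                                 paste0("f", qfreq)))))
    }
  }
  out
}

#' Gait-event features for one axis of one device
#'
#' Fifty-one features: step count, step frequency (count/duration), total
#' step distance (per-axis position displacement summed over retained
#' steps), and eight summary statistics of six per-step quantities measured
#' within each inter-step window: inter-step interval, step velocity, step
#' distance, and the path length of acceleration, velocity and position.
#'
#' @param stack a `kinematic_stack`
#' @param steps a `step_series` from [detect_steps()]
#' @param axis `"x"`, `"y"` or `"z"`
#' @return named numeric vector of length 51
#' @export
gait_event_features <- function(stack, steps, axis = "x") {
  t <- stack$accel$t
  duration <- diff(range(t))
  st <- steps$step_times
  n_steps <- length(st)
  base <- c(step_count = n_steps, step_freq = n_steps / duration)
  quantities <- list(isi = numeric(0), step_vel = numeric(0),
                     step_dist = numeric(0), pathlen_accel = numeric(0),
                     pathlen_vel = numeric(0), pathlen_pos = numeric(0))
  if (n_steps >= 2) {
    a <- stack$accel[[axis]]; v <- stack$velocity[[axis]]; p <- stack$position[[axis]]
    for (k in seq_len(n_steps - 1)) {
      w <- which(t >= st[k] & t <= st[k + 1])
      if (length(w) < 2) next
      dt <- st[k + 1] - st[k]
      dist <- abs(p[w[length(w)]] - p[w[1]])
      quantities$isi <- c(quantities$isi, dt * 1000)
      quantities$step_vel <- c(quantities$step_vel, dist / dt)
      quantities$step_dist <- c(quantities$step_dist, dist)
      quantities$pathlen_accel <- c(quantities$pathlen_accel, path_length(a[w]))
      quantities$pathlen_vel <- c(quantities$pathlen_vel, path_length(v[w]))
      quantities$pathlen_pos <- c(quantities$pathlen_pos, path_length(p[w]))
    }
  }
  out <- c(base, step_dist_total = sum(quantities$step_dist))
  for (qn in names(quantities)) {
    out <- c(out, setNames(stats8(quantities[[qn]]), paste0(qn, ".", TIME_STATS8)))
  }
  out
}

# Full 231-feature per-device catalog on one preprocessed trace.
motion_catalog_231 <- function(trace) {
  stack <- integrate_kinematics(trace)
  fs <- sampling_rate(trace$t)
  out <- c()
  for (axis in c("x", "y", "z")) {
    ut <- univariate_time_features(stack$accel[[axis]], stack$velocity[[axis]],
                                   stack$position[[axis]], stack$accel$t)
    out <- c(out, setNames(ut, paste0(axis, ".time.", names(ut))))
  }
  mv <- multivariate_time_features(stack)
  out <- c(out, setNames(mv, paste0("multi.", names(mv))))
  for (axis in c("x", "y", "z")) {
    uf <- univariate_frequency_features(stack$accel[[axis]], fs)
    out <- c(out, setNames(uf, paste0(axis, ".freq.", names(uf))))
  }
  out
}

na_like <- function(names) setNames(rep(NA_real_, length(names)), names)

# Catalog names computed once so missing payloads still emit every feature
# name with a missing value (never silently dropped).
motion_231_names <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- motion_trace(seq(0, 6, by = 0.01),
                         sin(seq(0, 6, by = 0.01) * 7) + 0.01,
                         cos(seq(0, 6, by = 0.01) * 9),
                         rep(-1, 601), frame = "geospatial")
      cache <<- names(motion_catalog_231(tr))
    }
    cache
  }
})

#' Extract the tremor feature set from a session payload
#'
#' 231 features per sub-task (postural, resting), 462 in total. Missing
#' sub-payloads yield named missing values.
#'
#' @param payload tremor payload: list with `postural` and `resting`
#'   device-frame `motion_trace` elements (or `NULL`)
#' @return named numeric vector of length 462
#' @export
extract_tremor <- function(payload) {
  out <- c()
  for (sub in c("postural", "resting")) {
    prefix <- paste0("tremor.", sub, ".watch.")
    tr <- payload[[sub]]
    vals <- if (is.null(tr)) {
      na_like(motion_231_names())
    } else {
      motion_catalog_231(rotate_to_geospatial(tr))
    }
    out <- c(out, setNames(vals, paste0(prefix, names(vals))))
  }
  out
}

#' Extract the gait-and-balance feature set from a session payload
#'
#' Per task (gait, balance): the 231-feature catalog on each device (462),
#' 285 cross-device coherence features, and 51 gait-event features per axis
#' per device (306) — 1053 per task, 2106 in total. Balance records run the
#' identical catalog (with near-zero step counts expected).
#'
#' @param payload gait/balance payload: list with `gait` and `balance`,
#'   each a list of device-frame `watch`/`phone` traces
#' @return named numeric vector of length 2106
#' @export
extract_gaitbalance <- function(payload) {
  out <- c()
  qnames51 <- names(gait_event_features(
    integrate_kinematics(motion_trace(seq(0, 6, by = 0.02),
                                      rep(0.01, 301), rep(0.01, 301),
                                      rep(-1, 301), frame = "geospatial")),
    structure(list(step_times = numeric(0), inter_step_intervals = numeric(0),
                   excluded_count = 0L), class = "step_series")))
  coh_names <- NULL
  for (task in c("gait", "balance")) {
    prefix <- paste0("gait_balance.", task, ".")
    sub <- payload[[task]]
    if (is.null(sub)) {
      for (dev in c("watch", "phone")) {
        out <- c(out, na_like(paste0(prefix, dev, ".",
                                     motion_231_names())))
      }
      if (is.null(coh_names)) coh_names <- coherence_feature_names()
      out <- c(out, na_like(paste0(prefix, "coh.", coh_names)))
      for (dev in c("watch", "phone")) {
        for (axis in c("x", "y", "z")) {
          out <- c(out, na_like(paste0(prefix, dev, ".", axis, ".gait.", qnames51)))
        }
      }
      next
    }
    rot <- list(watch = rotate_to_geospatial(sub$watch),
                phone = rotate_to_geospatial(sub$phone))
    for (dev in c("watch", "phone")) {
      vals <- motion_catalog_231(rot[[dev]])
      out <- c(out, setNames(vals, paste0(prefix, dev, ".", names(vals))))
    }
    sync <- synchronize(rot$watch, rot$phone)
    coh <- coherence_features(sync$watch, sync$phone)
    out <- c(out, setNames(coh, paste0(prefix, "coh.", names(coh))))
    for (dev in c("watch", "phone")) {
      stack <- integrate_kinematics(rot[[dev]])
      steps <- detect_steps(rot[[dev]])
      for (axis in c("x", "y", "z")) {
        ge <- gait_event_features(stack, steps, axis)
        out <- c(out, setNames(ge, paste0(prefix, dev, ".", axis, ".gait.", names(ge))))
      }
    }
  }
  out
}

coherence_feature_names <- function() {
  nm <- c("watch.x", "watch.y", "watch.z", "phone.x", "phone.y", "phone.z")
  qfreq <- c(1:10, 15, 20, 25, 30, 35, 40, 45)
  out <- character(0)
  for (i in 1:5) for (j in (i + 1):6) {
    out <- c(out, paste0(nm[i], "_", nm[j], ".",
                         c("peak_freq", "total", paste0("f", qfreq))))
  }
  out
}
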